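# Reduction of supernatant-depletion time courses to uptake rates per
# biomass, and %-remaining curves.
#
# Assays travel as a long-format data frame with one row per measured time
# point: sugar, condition, replicate, volume_L, biomass_mg, time_min,
# conc_uM. A single assay (one sugar/condition/replicate) is a list with
# those fields, time_min and conc_uM being parallel vectors.

TIME_TOL <- 1e-6

#' Construct a single uptake assay record
#'
#' @param sugar,condition Character labels.
#' @param replicate Integer replicate id.
#' @param volume_L Assay volume in litres (> 0).
#' @param biomass_mg Mycelial dry weight in mg (> 0).
#' @param time_min Strictly increasing time points (min), starting at 0.
#' @param conc_uM Supernatant sugar concentrations (uM), same length.
#' @return Object of class `uptake_assay`.
#' @export
uptake_assay <- function(sugar, condition, replicate, volume_L, biomass_mg,
                         time_min, conc_uM) {
  if (volume_L <= 0) stop("volume_L must be > 0")
  if (biomass_mg <= 0) stop("biomass_mg must be > 0")
  if (length(time_min) != length(conc_uM) || length(time_min) < 2L)
    stop("time_min and conc_uM must have equal length >= 2")
  if (any(diff(time_min) <= 0)) stop("time points must be strictly increasing")
  if (abs(time_min[1L]) > TIME_TOL) stop("time course must start at 0")
  if (any(conc_uM < 0)) stop("concentrations must be nonnegative")
  structure(list(sugar = sugar, condition = condition,
                 replicate = as.integer(replicate),
                 volume_L = volume_L, biomass_mg = biomass_mg,
                 time_min = as.numeric(time_min), conc_uM = as.numeric(conc_uM)),
            class = "uptake_assay")
}

#' Split a long-format assay table into assay records
#'
#' @param df Data frame with columns sugar, condition, replicate, volume_L,
#'   biomass_mg, time_min, conc_uM (one row per time point).
#' @return List of `uptake_assay` objects, ordered by first appearance.
#' @export
as_uptake_assays <- function(df) {
  if (inherits(df, "uptake_assay")) return(list(df))
  if (is.list(df) && !is.data.frame(df) &&
      all(vapply(df, inherits, logical(1), "uptake_assay"))) return(df)
  need <- c("sugar", "condition", "replicate", "volume_L", "biomass_mg",
            "time_min", "conc_uM")
  if (!all(need %in% names(df)))
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$sugar, df$condition, df$replicate, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    uptake_assay(sub$sugar[1L], sub$condition[1L], sub$replicate[1L],
                 sub$volume_L[1L], sub$biomass_mg[1L],
                 sub$time_min, sub$conc_uM)
  })
}

#' Read uptake assays from a long-format CSV
#'
#' @param path CSV path (columns as in [as_uptake_assays()]).
#' @return List of `uptake_assay` objects.
#' @export
read_assays_csv <- function(path) {
  as_uptake_assays(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write uptake assays to a long-format CSV
#'
#' @param assays List of `uptake_assay` objects or a long-format data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assays_csv <- function(assays, path) {
  df <- assays_to_long(assays)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

assays_to_long <- function(assays) {
  if (is.data.frame(assays)) return(assays)
  do.call(rbind, lapply(as_uptake_assays(assays), function(a) {
    data.frame(sugar = a$sugar, condition = a$condition,
               replicate = a$replicate, volume_L = a$volume_L,
               biomass_mg = a$biomass_mg, time_min = a$time_min,
               conc_uM = a$conc_uM, stringsAsFactors = FALSE)
  }))
}

#' Two-point uptake rate from a depletion time course
#'
#' Computes the uptake rate per biomass between time 0 and `t_end_min`:
#' `rate = (C(0) - C(t_end)) * volume_L * 1000 / (t_end * biomass_mg)`
#' in nmol min^-1 mg DW^-1 (concentrations in uM). A negative raw rate
#' (supernatant concentration increased, e.g. evaporation exceeding uptake
#' for a non-transported sugar) is reported as-is and flagged
#' `negative`; clipping to zero happens only during aggregation into the
#' rate matrix.
#'
#' @param assay An `uptake_assay`.
#' @param t_end_min End point of the rate window (default 15 min). Both 0
#'   and `t_end_min` must be present in the time course (matched to 1e-6).
#' @return List with `rate` (nmol min^-1 mg^-1), `flag` (`"none"` or
#'   `"negative"`), `sugar`, `condition`, `replicate`.
#' @export
compute_uptake_rate <- function(assay, t_end_min = 15) {
  if (!inherits(assay, "uptake_assay")) assay <- as_uptake_assays(assay)[[1L]]
  i0 <- which(abs(assay$time_min - 0) <= TIME_TOL)
  i1 <- which(abs(assay$time_min - t_end_min) <= TIME_TOL)
  if (length(i0) != 1L || length(i1) != 1L)
    stop(sprintf("assay %s/%s rep %d lacks time point 0 or %g min",
                 assay$sugar, assay$condition, assay$replicate, t_end_min))
  if (assay$biomass_mg <= 0) stop("nonpositive biomass")
  dC <- assay$conc_uM[i0] - assay$conc_uM[i1]          # uM depleted
  rate <- dC * assay$volume_L * 1000 / (t_end_min * assay$biomass_mg)
  list(rate = rate, flag = if (rate < 0) "negative" else "none",
       sugar = assay$sugar, condition = assay$condition,
       replicate = assay$replicate)
}

#' Aggregate assays into a sugar x condition uptake-rate matrix
#'
#' Each cell is the arithmetic mean of the replicate rates for that
#' (sugar, condition); negative replicate rates are clipped to 0 before
#' averaging and the cell is flagged `negative_clipped`. Row and column
#' order follow first appearance in the input. Design cells with no assay
#' are `NA`, not zero.
#'
#' @param assays List of `uptake_assay` objects or a long-format data frame.
#' @param t_end_min Rate window end point (default 15 min).
#' @return Object of class `uptake_matrix`: list with `rates` (matrix,
#'   nmol min^-1 mg^-1), `n_replicates` (integer matrix), `flags`
#'   (character matrix, comma-joined flag sets, `""` when clean).
#' @export
build_uptake_matrix <- function(assays, t_end_min = 15) {
  assays <- as_uptake_assays(assays)
  if (length(assays) == 0L) stop("no assays supplied")
  res <- lapply(assays, compute_uptake_rate, t_end_min = t_end_min)
  sugars <- unique(vapply(res, `[[`, "", "sugar"))
  conds <- unique(vapply(res, `[[`, "", "condition"))
  rates <- matrix(NA_real_, length(sugars), length(conds),
                  dimnames = list(sugars, conds))
  nrep <- matrix(0L, length(sugars), length(conds),
                 dimnames = list(sugars, conds))
  flags <- matrix("", length(sugars), length(conds),
                  dimnames = list(sugars, conds))
  acc <- list()
  for (r in res) {
    k <- paste(r$sugar, r$condition, sep = "\r")
    acc[[k]] <- c(acc[[k]], list(r))
  }
  for (k in names(acc)) {
    rs <- vapply(acc[[k]], `[[`, 0, "rate")
    fl <- character(0)
    if (any(rs < 0)) fl <- "negative_clipped"
    s <- acc[[k]][[1L]]$sugar; cn <- acc[[k]][[1L]]$condition
    rates[s, cn] <- mean(pmax(rs, 0))
    nrep[s, cn] <- length(rs)
    flags[s, cn] <- paste(fl, collapse = ",")
  }
  structure(list(rates = rates, n_replicates = nrep, flags = flags),
            class = "uptake_matrix")
}

#' @export
print.uptake_matrix <- function(x, ...) {
  cat("uptake rate matrix [nmol min^-1 mg DW^-1]:",
      nrow(x$rates), "sugars x", ncol(x$rates), "conditions\n")
  print(round(x$rates, 3))
  nf <- sum(nzchar(x$flags))
  if (nf > 0) cat(nf, "flagged cell(s)\n")
  invisible(x)
}

#' Write an uptake-rate matrix as TSV (+ flag sidecar JSON)
#'
#' @param um An `uptake_matrix`.
#' @param path TSV output path; flags go to `paste0(path, ".flags.json")`.
#' @return `path`, invisibly.
#' @export
write_uptake_tsv <- function(um, path) {
  stopifnot(inherits(um, "uptake_matrix"))
  df <- data.frame(sugar = rownames(um$rates), um$rates, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  flagged <- which(matrix(nzchar(um$flags), nrow(um$flags)), arr.ind = TRUE)
  fl <- lapply(seq_len(nrow(flagged)), function(k) {
    ij <- flagged[k, ]
    list(sugar = rownames(um$flags)[ij[1L]],
         condition = colnames(um$flags)[ij[2L]],
         flags = strsplit(um$flags[ij[1L], ij[2L]], ",")[[1L]])
  })
  jsonlite::write_json(unname(fl), paste0(path, ".flags.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an uptake-rate matrix from TSV
#'
#' @param path TSV written by [write_uptake_tsv()] (first column `sugar`).
#' @return An `uptake_matrix` (flags empty, `n_replicates` set to 1 where a
#'   rate is present).
#' @export
read_uptake_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  structure(list(rates = m,
                 n_replicates = matrix(ifelse(is.na(m), 0L, 1L), nrow(m),
                                       ncol(m), dimnames = dimnames(m)),
                 flags = matrix("", nrow(m), ncol(m), dimnames = dimnames(m))),
            class = "uptake_matrix")
}

#' Percent of sugar remaining in the supernatant over time
#'
#' For each replicate, reports `100 * C(t) / C(0)`; the value at time 0 is
#' exactly 100. This is the quantity conventionally plotted for depletion
#' curves ("% remaining"), the complement of percent taken up.
#'
#' @param assays List of `uptake_assay` objects or a long-format data frame.
#' @param sugar,condition Which cell of the design to extract.
#' @return Matrix, time points (rows, named by time in min) x replicates.
#' @export
percent_remaining <- function(assays, sugar, condition) {
  assays <- as_uptake_assays(assays)
  sel <- Filter(function(a) a$sugar == sugar && a$condition == condition,
                assays)
  if (length(sel) == 0L)
    stop("no assays for ", sugar, " / ", condition)
  times <- sort(unique(unlist(lapply(sel, `[[`, "time_min"))))
  out <- matrix(NA_real_, length(times), length(sel),
                dimnames = list(format(times, trim = TRUE),
                                vapply(sel, function(a)
                                  paste0("rep", a$replicate), "")))
  for (j in seq_along(sel)) {
    a <- sel[[j]]
    if (a$conc_uM[1L] <= 0) stop("C(0) must be > 0 for percent_remaining")
    idx <- match(round(a$time_min, 6), round(times, 6))
    out[idx, j] <- 100 * a$conc_uM / a$conc_uM[1L]
  }
  out
}
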