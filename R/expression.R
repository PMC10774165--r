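# Expression-matrix ingestion and transforms, plus 2^-ddCt quantification.
#
# An expression matrix is an ordinary numeric matrix with transporter genes in
# rows and induction conditions in columns (arbitrary expression units,
# nonnegative before transformation).

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column (`gene`) holds row labels
#' and whose header row holds condition labels.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows, conditions in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene column plus at least one condition")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  check_numeric_matrix(m, "expression matrix")
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with gene row names and condition column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  check_numeric_matrix(m, "expression matrix")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform an expression or uptake matrix
#'
#' Applies `log2(value + pseudocount)` cell-wise. Shape and dimnames are
#' preserved. The transform is strictly monotone per cell.
#'
#' @param m Numeric matrix.
#' @param pseudocount Added before taking logs; default 1 so that zero maps
#'   to zero. Must satisfy `value + pseudocount > 0` everywhere.
#' @return Transformed matrix.
#' @export
log_transform <- function(m, pseudocount = 1) {
  check_numeric_matrix(m, "matrix")
  if (any(m + pseudocount <= 0))
    stop("log_transform: value + pseudocount <= 0 encountered")
  out <- log2(m + pseudocount)
  dimnames(out) <- dimnames(m)
  out
}

#' Standardize matrix rows to zero mean and unit variance
#'
#' Each row is centred and scaled by its sample standard deviation (n - 1).
#' Constant rows cannot be scaled; they are mapped to all-zeros and flagged
#' in the `"constant_rows"` attribute rather than dropped, so that weakly or
#' constitutively expressed genes survive to downstream reports.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @return Matrix of z-scored rows with attribute `constant_rows` (character
#'   vector of flagged row labels, possibly empty).
#' @export
standardize_rows <- function(m) {
  check_numeric_matrix(m, "matrix")
  if (ncol(m) < 2L) stop("standardize_rows needs >= 2 conditions")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  out <- (m - mu) / sdv
  out[const, ] <- 0
  dimnames(out) <- dimnames(m)
  attr(out, "constant_rows") <- rownames(m)[const]
  out
}

#' Read a qPCR Ct table from CSV
#'
#' Columns: `sample_id`, `group` (`treatment`/`calibrator`), `gene`
#' (`target`/`reference`), and the technical triplicate `ct1`, `ct2`, `ct3`.
#'
#' @param path CSV path.
#' @return Data frame with the columns above.
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_qpcr_table(df)
  df
}

#' Write a qPCR Ct table to CSV
#'
#' @param q qPCR table data frame (see [read_qpcr_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_csv <- function(q, path) {
  validate_qpcr_table(q)
  utils::write.csv(q, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_qpcr_table <- function(q) {
  need <- c("sample_id", "group", "gene", "ct1", "ct2", "ct3")
  if (!all(need %in% names(q)))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  if (!all(q$group %in% c("treatment", "calibrator")))
    stop("qPCR group must be 'treatment' or 'calibrator'")
  if (!all(q$gene %in% c("target", "reference")))
    stop("qPCR gene must be 'target' or 'reference'")
  invisible(q)
}

#' Relative quantification by the 2^-ddCt method
#'
#' For each sample, dCt is the mean of the target Ct triplicate minus the
#' mean of the reference-gene Ct triplicate (expression normalized to the
#' reference, e.g. actin). ddCt is the mean treatment dCt minus the mean
#' calibrator dCt, and the fold change is `2^(-ddCt)`. The per-group
#' standard error is computed from the per-sample dCt values (sample sd,
#' n - 1), following the convention of propagating error on dCt rather than
#' on the exponentiated fold.
#'
#' @param q qPCR table data frame (see [read_qpcr_csv()]). Every sample must
#'   carry both a target and a reference row.
#' @return List with `fold_change`, `ddct`, `dct_mean` (named per group),
#'   `se_dct` (named per group), and `per_sample` (data frame of sample dCt).
#' @export
ddct_fold_change <- function(q) {
  validate_qpcr_table(q)
  ct <- rowMeans(as.matrix(q[, c("ct1", "ct2", "ct3")]))
  samples <- unique(q$sample_id)
  per <- lapply(samples, function(s) {
    rows <- q$sample_id == s
    tg <- ct[rows & q$gene == "target"]
    rf <- ct[rows & q$gene == "reference"]
    if (length(tg) != 1L || length(rf) != 1L)
      stop("sample ", s, " must have exactly one target and one reference row")
    data.frame(sample_id = s, group = q$group[rows][1L], dct = tg - rf,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  for (g in c("treatment", "calibrator"))
    if (!any(per$group == g)) stop("no samples in group '", g, "'")
  dct_mean <- tapply(per$dct, per$group, mean)
  se <- tapply(per$dct, per$group, function(x)
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_)
  ddct <- unname(dct_mean["treatment"] - dct_mean["calibrator"])
  list(fold_change = 2^(-ddct),
       ddct = ddct,
       dct_mean = dct_mean[c("treatment", "calibrator")],
       se_dct = se[c("treatment", "calibrator")],
       per_sample = per)
}
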