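# Synthetic transportome generator.
#
# The generative model mirrors the assumptions of the expression-uptake
# correlation analysis: a transporter's expression is a condition-specific
# snapshot (basal level x fold-induction on its inducing conditions, x a
# carbon-catabolite-repression factor on the repressing condition), and the
# true uptake rate of a sugar in a condition is the sum of the individual
# transporter contributions,
#   uptake_true(s, c) = sum_t A(t, s) * act(t, c),
# where act(t, c) equals the expression E(t, c) for transcriptionally
# coupled transporters and a condition-independent constant for decoupled
# (post-transcriptionally regulated, FRT-1-like) ones. Observed uptake adds
# multiplicative lognormal noise per cell.

DEFAULT_CONDITIONS <- c("no_carbon", "sucrose", "galactose",
                        "galacturonic_acid", "glucose", "mannose", "xylose",
                        "arabinose", "rhamnose", "arabinan", "cellulose",
                        "glucomannan", "pectin", "xylan", "maltose")

DEFAULT_SUGARS <- c("galactose", "galacturonic_acid", "glucose", "mannose",
                    "xylose", "arabinose", "rhamnose", "cellobiose",
                    "lactose", "mannobiose")

#' Specify a synthetic transportome
#'
#' Bundles everything the simulator needs: the activity matrix `A(t, s)`
#' (nonnegative transport capacity per unit expression, nmol min^-1 mg^-1
#' per expression unit), per-transporter induction (which conditions induce,
#' and by what fold), basal expression, carbon-catabolite repression under a
#' repressing condition, sets of expression-decoupled and constitutive
#' transporters, and the observation noise level.
#'
#' @param activity Matrix, transporters x sugars, entries >= 0; every sugar
#'   column needs at least one positive entry. Row/column names name the
#'   transporters and sugars.
#' @param conditions Ordered condition labels (default: 15 labels including
#'   a no-carbon control and a repressing sucrose condition).
#' @param induction Named list transporter -> named numeric vector of
#'   fold-induction factors keyed by inducing condition. Transporters
#'   missing from the list stay at basal expression.
#' @param basal_expression Positive basal expression per transporter
#'   (scalar or named vector; default 1).
#' @param ccr_condition Condition under which CCR-subject transporters are
#'   repressed (`NULL` disables CCR; default `"sucrose"` when present).
#' @param ccr_factor Multiplicative repression factor in (0, 1].
#' @param ccr_transporters Transporters subject to CCR (default: all
#'   non-constitutive ones).
#' @param decoupled Names of transporters whose activity ignores expression
#'   (constant activity `decoupled_activity`).
#' @param decoupled_activity Constant activity level for decoupled
#'   transporters (scalar or named vector; default: their basal expression).
#' @param constitutive Names of transporters with induction-independent
#'   expression (basal everywhere, exempt from CCR).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   observation noise on uptake (>= 0).
#' @param seed Integer seed for all randomness downstream of this spec.
#' @return Object of class `transportome_spec`.
#' @export
transportome_spec <- function(activity,
                              conditions = DEFAULT_CONDITIONS,
                              induction = list(),
                              basal_expression = 1,
                              ccr_condition = if ("sucrose" %in% conditions)
                                "sucrose" else NULL,
                              ccr_factor = 0.2,
                              ccr_transporters = NULL,
                              decoupled = character(0),
                              decoupled_activity = NULL,
                              constitutive = character(0),
                              noise_cv = 0.1,
                              seed = 1) {
  check_numeric_matrix(activity, "activity matrix")
  if (any(activity < 0)) stop("activity entries must be >= 0")
  transporters <- rownames(activity)
  sugars <- colnames(activity)
  if (any(colSums(activity) == 0)) {
    orphan <- sugars[colSums(activity) == 0]
    stop("orphan sugar has no transporter: ", paste(orphan, collapse = ", "))
  }
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  basal <- rep_len(basal_expression, length(transporters))
  if (!is.null(names(basal_expression)))
    basal <- basal_expression[transporters]
  names(basal) <- transporters
  if (any(basal <= 0)) stop("basal expression must be > 0")
  bad <- setdiff(names(induction), transporters)
  if (length(bad)) stop("induction for unknown transporters: ",
                        paste(bad, collapse = ", "))
  for (tn in names(induction)) {
    iv <- induction[[tn]]
    if (is.null(names(iv)) || !all(names(iv) %in% conditions))
      stop("induction conditions for ", tn, " must name known conditions")
    if (any(iv <= 0)) stop("fold-induction factors must be > 0")
  }
  if (!is.null(ccr_condition) && !(ccr_condition %in% conditions))
    stop("ccr_condition not among condition labels")
  if (ccr_factor <= 0 || ccr_factor > 1) stop("ccr_factor must be in (0, 1]")
  stopifnot(all(decoupled %in% transporters),
            all(constitutive %in% transporters))
  if (is.null(ccr_transporters))
    ccr_transporters <- setdiff(transporters, constitutive)
  stopifnot(all(ccr_transporters %in% transporters))
  dact <- basal[decoupled]
  if (!is.null(decoupled_activity)) {
    dact <- rep_len(decoupled_activity, length(decoupled))
    if (!is.null(names(decoupled_activity)))
      dact <- decoupled_activity[decoupled]
    names(dact) <- decoupled
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(activity = activity, conditions = conditions,
                 transporters = transporters, sugars = sugars,
                 induction = induction, basal_expression = basal,
                 ccr_condition = ccr_condition, ccr_factor = ccr_factor,
                 ccr_transporters = ccr_transporters,
                 decoupled = decoupled, decoupled_activity = dact,
                 constitutive = constitutive,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "transportome_spec")
}

#' @export
print.transportome_spec <- function(x, ...) {
  cat("transportome spec:", length(x$transporters), "transporters,",
      length(x$sugars), "sugars,", length(x$conditions), "conditions\n")
  cat("  decoupled:", if (length(x$decoupled))
    paste(x$decoupled, collapse = ", ") else "none",
    "| constitutive:", if (length(x$constitutive))
      paste(x$constitutive, collapse = ", ") else "none", "\n")
  cat("  noise_cv:", x$noise_cv, " seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate expression and uptake from a transportome spec
#'
#' Deterministic given the spec's seed. Expression is basal x fold-induction
#' on inducing conditions, x the CCR factor on the repressing condition;
#' constitutive transporters sit at basal everywhere. True uptake follows
#' the additive model (see the package vignette); observed uptake multiplies
#' each cell by independent lognormal noise with CV `noise_cv`. Assignment
#' shares attribute each sugar to its contributing transporters in
#' proportion to their mean contribution across conditions (summing to 1).
#'
#' @param spec A `transportome_spec`.
#' @return Object of class `transportome_truth`: list with `spec`,
#'   `expression` (genes x conditions), `activity_profile` (what uptake
#'   actually responds to), `uptake_true`, `uptake_observed` (sugars x
#'   conditions, nmol min^-1 mg^-1), and `assignment` (named list sugar ->
#'   named share vector).
#' @export
simulate_transportome <- function(spec) {
  stopifnot(inherits(spec, "transportome_spec"))
  tr <- spec$transporters; cn <- spec$conditions; sg <- spec$sugars
  E <- matrix(rep(spec$basal_expression, length(cn)), length(tr), length(cn),
              dimnames = list(tr, cn))
  for (tn in setdiff(names(spec$induction), spec$constitutive)) {
    iv <- spec$induction[[tn]]
    E[tn, names(iv)] <- E[tn, names(iv)] * iv
  }
  if (!is.null(spec$ccr_condition)) {
    rep_t <- setdiff(spec$ccr_transporters, spec$constitutive)
    E[rep_t, spec$ccr_condition] <- E[rep_t, spec$ccr_condition] *
      spec$ccr_factor
  }
  act <- E
  for (tn in spec$decoupled) act[tn, ] <- spec$decoupled_activity[[tn]]
  uptake_true <- t(spec$activity) %*% act
  dimnames(uptake_true) <- list(sg, cn)
  noise <- withr::with_seed(spec$seed,
    matrix(lognormal_noise(length(uptake_true), spec$noise_cv),
           nrow(uptake_true), ncol(uptake_true)))
  uptake_observed <- uptake_true * noise
  contrib <- spec$activity * rowMeans(act)        # mean contribution per t
  assignment <- lapply(sg, function(s) {
    sh <- contrib[, s]
    sh <- sh[sh > 0]
    sh / sum(sh)
  })
  names(assignment) <- sg
  structure(list(spec = spec, expression = E, activity_profile = act,
                 uptake_true = uptake_true, uptake_observed = uptake_observed,
                 assignment = assignment),
            class = "transportome_truth")
}

#' @export
print.transportome_truth <- function(x, ...) {
  cat("simulated transportome truth:", nrow(x$expression), "genes,",
      nrow(x$uptake_true), "sugars,", ncol(x$expression), "conditions",
      sprintf("(noise_cv = %g, seed = %d)\n", x$spec$noise_cv, x$spec$seed))
  invisible(x)
}

#' Simulate supernatant-depletion uptake assays
#'
#' For every (sugar, condition) cell of the truth's rate matrix and each
#' replicate, generates a two-point time course at t = 0 and `t_end_min`
#' with `C(t_end) = C(0) - rate * t_end * biomass_mg / (volume_L * 1000)`
#' (concentrations in uM), where the replicate rate is the true rate times
#' lognormal noise with CV `noise_cv`. An implied negative concentration is
#' clamped to 0 and the assay flagged `depleted` (retrievable via the
#' `depleted` attribute). With `noise_cv = 0` and no depletion,
#' [compute_uptake_rate()] inverts these assays to the true rates exactly.
#'
#' @param truth A `transportome_truth`.
#' @param volume_L Assay volume (default 0.003 L, i.e. 3 mL).
#' @param biomass_mg Dry weight per replicate (default 2 mg).
#' @param c0_uM Starting concentration (default 100 uM).
#' @param n_replicates Biological replicates per cell (default 3).
#' @param t_end_min Second time point (default 15 min).
#' @param noise_cv Replicate-level CV on the rate (default 0: noise-free).
#' @param seed Integer seed.
#' @return List of `uptake_assay` objects with attribute `depleted` (data
#'   frame of flagged sugar/condition/replicate, possibly empty).
#' @export
simulate_uptake_assays <- function(truth, volume_L = 0.003, biomass_mg = 2,
                                   c0_uM = 100, n_replicates = 3,
                                   t_end_min = 15, noise_cv = 0, seed = 1) {
  stopifnot(inherits(truth, "transportome_truth"))
  if (volume_L <= 0 || biomass_mg <= 0 || c0_uM <= 0)
    stop("volume_L, biomass_mg and c0_uM must be > 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  rates <- truth$uptake_true
  assays <- list()
  depleted <- list()
  withr::with_seed(seed, {
    for (s in rownames(rates)) for (cn in colnames(rates)) {
      fac <- lognormal_noise(n_replicates, noise_cv)
      for (rep in seq_len(n_replicates)) {
        r <- rates[s, cn] * fac[rep]
        c_end <- c0_uM - r * t_end_min * biomass_mg / (volume_L * 1000)
        if (c_end < 0) {
          c_end <- 0
          depleted[[length(depleted) + 1L]] <-
            data.frame(sugar = s, condition = cn, replicate = rep,
                       stringsAsFactors = FALSE)
        }
        assays[[length(assays) + 1L]] <-
          uptake_assay(s, cn, rep, volume_L, biomass_mg,
                       c(0, t_end_min), c(c0_uM, c_end))
      }
    }
  })
  attr(assays, "depleted") <- if (length(depleted))
    do.call(rbind, depleted) else
      data.frame(sugar = character(0), condition = character(0),
                 replicate = integer(0))
  assays
}

#' Simulate an amino-acid alignment down a tree
#'
#' Evolves i.i.d. sites under the equal-rate 20-state (Poisson) amino-acid
#' model: along a branch of length `b` expected substitutions per site, a
#' site retains its endpoint state with probability `exp(-20 b / 19)` and is
#' otherwise redrawn uniformly from the 20 residues (so the probability of
#' observing the same residue is `1/20 + (19/20) exp(-20 b / 19)`).
#' Optionally, a fraction of sites per sequence is replaced by gaps,
#' uniformly at random.
#'
#' @param tree A `phylo` tree with branch lengths in expected substitutions
#'   per site.
#' @param n_sites Number of alignment columns (> 0).
#' @param seed Integer seed.
#' @param gap_fraction Per-sequence fraction of sites turned into `-`.
#' @return Named character vector of aligned sequences (tips of `tree`).
#' @export
simulate_alignment <- function(tree, n_sites, seed = 1, gap_fraction = 0) {
  if (n_sites < 1L) stop("n_sites must be positive")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- n + 1L
  seqs <- vector("list", n + nnode)
  withr::with_seed(seed, {
    seqs[[root]] <- sample(AA_ALPHABET, n_sites, replace = TRUE)
    pre <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]; b <- pre$edge.length[e]
      s <- seqs[[p]]
      hit <- stats::runif(n_sites) > exp(-20 * b / 19)
      if (any(hit)) s[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
      seqs[[ch]] <- s
    }
    out <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""), "")
    names(out) <- tree$tip.label
    if (gap_fraction > 0) {
      ngap <- round(gap_fraction * n_sites)
      for (i in seq_len(n)) {
        pos <- sample.int(n_sites, ngap)
        v <- strsplit(out[[i]], "")[[1L]]
        v[pos] <- "-"
        out[[i]] <- paste(v, collapse = "")
      }
    }
    out
  })
}

#' Simulate a two-group qPCR Ct table
#'
#' Builds `n_samples` treatment and `n_samples` calibrator samples with one
#' target and one reference-gene row each (technical Ct triplicates). The
#' calibrator dCt is `base_dct`; the treatment dCt is shifted by
#' `-log2(true_fold)`, so that [ddct_fold_change()] on noise-free output
#' returns `true_fold` exactly.
#'
#' @param n_samples Biological samples per group (>= 1).
#' @param true_fold True fold change, > 0.
#' @param ref_ct_mean Mean reference-gene Ct (default 18).
#' @param seed Integer seed.
#' @param sd_ct Additive Gaussian technical noise on every Ct (default 0).
#' @param base_dct Calibrator-group dCt (default 2).
#' @return qPCR table data frame (see [read_qpcr_csv()]).
#' @export
simulate_qpcr <- function(n_samples, true_fold, ref_ct_mean = 18, seed = 1,
                          sd_ct = 0, base_dct = 2) {
  if (true_fold <= 0) stop("true_fold must be > 0")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  rows <- list()
  withr::with_seed(seed, {
    for (g in c("treatment", "calibrator")) {
      dct <- if (g == "treatment") base_dct - log2(true_fold) else base_dct
      for (i in seq_len(n_samples)) {
        sid <- paste0(g, "_", i)
        ref_ct <- ref_ct_mean + stats::rnorm(3, 0, sd_ct)
        tgt_ct <- ref_ct_mean + dct + stats::rnorm(3, 0, sd_ct)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = "target",
          ct1 = tgt_ct[1L], ct2 = tgt_ct[2L], ct3 = tgt_ct[3L],
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g, gene = "reference",
          ct1 = ref_ct[1L], ct2 = ref_ct[2L], ct3 = ref_ct[3L],
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}

#' Fungal-transportome-like preset spec
#'
#' A 44-transporter, 10-sugar, 15-condition scenario shaped like the
#' filamentous-fungus setting the method was designed for. Ten focal
#' transporters carry the ten sugars; the remainder are background genes
#' with seeded two-condition induction patterns and no activity on the
#' assayed sugars. Features (all switchable):
#'
#' * `dedicated_only = TRUE`: strictly one dedicated transporter per sugar
#'   (diagonal activity) — the benchmark configuration for assignment
#'   recovery.
#' * Default (`FALSE`): adds functional redundancy and promiscuity — an
#'   arabinose transporter also carrying part of galactose, a
#'   galacturonic-acid transporter induced by its substrate and pectin, two
#'   cellodextrin-like transporters sharing cellobiose/mannobiose/lactose,
#'   and a minor lactose/galactose contributor induced by arabinose and
#'   galactose.
#' * `decoupled = TRUE`: the rhamnose transporter becomes expression-
#'   decoupled (constant activity, induced only by an unrelated condition),
#'   emulating post-transcriptional regulation.
#' * Constitutive and weakly/never-induced background genes exercise the
#'   constant-row handling of the clustering stage.
#'
#' @param dedicated_only One dedicated transporter per sugar (default FALSE).
#' @param decoupled Make the rhamnose transporter expression-decoupled.
#' @param noise_cv Observation noise CV (default 0.1).
#' @param seed Integer seed (drives background induction patterns and all
#'   downstream noise).
#' @param fold Fold-induction factor on inducing conditions (default 20).
#' @return A `transportome_spec`.
#' @export
preset_neurospora_like <- function(dedicated_only = FALSE, decoupled = FALSE,
                                   noise_cv = 0.1, seed = 1, fold = 20) {
  conds <- DEFAULT_CONDITIONS
  sugars <- DEFAULT_SUGARS
  focal <- c(galactose = "gal1_like", galacturonic_acid = "gat1_like",
             glucose = "hgt1_like", mannose = "mnt1_like",
             xylose = "xyt1_like", arabinose = "lat1_like",
             rhamnose = "rht1_like", cellobiose = "cdt1_like",
             lactose = "cdt2_like", mannobiose = "ncu00809_like")
  extras <- c("glt1_like", "sut15_like", "ncu07054_like")
  n_bg <- 44L - length(focal) - length(extras)
  bg <- sprintf("stp%02d", seq_len(n_bg))
  transporters <- c(unname(focal), extras, bg)
  A <- matrix(0, length(transporters), length(sugars),
              dimnames = list(transporters, sugars))
  # inducing condition of each focal transporter's substrate; distinct per
  # transporter so no two dedicated expression profiles coincide
  induce_map <- c(galactose = "galactose", galacturonic_acid =
                    "galacturonic_acid", glucose = "glucose",
                  mannose = "mannose", xylose = "xylose",
                  arabinose = "arabinose", rhamnose = "rhamnose",
                  cellobiose = "cellulose", lactose = "xylan",
                  mannobiose = "glucomannan")
  induction <- list()
  if (dedicated_only) {
    for (s in sugars) {
      A[focal[[s]], s] <- 1
      induction[[focal[[s]]]] <- stats::setNames(fold, induce_map[[s]])
    }
  } else {
    A["lat1_like", "arabinose"] <- 1
    induction$lat1_like <- stats::setNames(c(fold, fold),
                                           c("arabinose", "arabinan"))
    A["gat1_like", "galacturonic_acid"] <- 1
    induction$gat1_like <- stats::setNames(c(fold, fold),
                                           c("galacturonic_acid", "pectin"))
    A["hgt1_like", "glucose"] <- 0.6
    A["glt1_like", "glucose"] <- 0.4
    induction$hgt1_like <- stats::setNames(c(fold, fold / 2),
                                           c("glucose", "maltose"))
    induction$glt1_like <- stats::setNames(c(fold, fold / 2),
                                           c("glucose", "maltose"))
    A["mnt1_like", "mannose"] <- 1
    induction$mnt1_like <- stats::setNames(c(fold, fold),
                                           c("mannose", "glucomannan"))
    A["xyt1_like", "xylose"] <- 1
    induction$xyt1_like <- stats::setNames(c(fold, fold),
                                           c("xylose", "xylan"))
    A["rht1_like", "rhamnose"] <- 1
    induction$rht1_like <- stats::setNames(fold, "rhamnose")
    # cellodextrin pair: shared, promiscuous disaccharide uptake
    A["cdt1_like", "cellobiose"] <- 0.5
    A["cdt2_like", "cellobiose"] <- 0.5
    A["cdt1_like", "mannobiose"] <- 0.3
    A["cdt2_like", "mannobiose"] <- 0.7
    A["cdt1_like", "lactose"] <- 0.45
    A["cdt2_like", "lactose"] <- 0.45
    A["ncu00809_like", "lactose"] <- 0.1
    induction$cdt1_like <- stats::setNames(fold, "cellulose")
    induction$cdt2_like <- stats::setNames(c(fold, fold / 2),
                                           c("cellulose", "xylan"))
    # minor lactose/galactose contributor induced by arabinose + galactose
    A["ncu00809_like", "galactose"] <- 0.6
    A["gal1_like", "galactose"] <- 0.4
    induction$ncu00809_like <- stats::setNames(c(fold, fold),
                                               c("arabinose", "galactose"))
    induction$gal1_like <- stats::setNames(fold, "galactose")
  }
  decoupled_set <- character(0)
  if (decoupled) {
    # rhamnose transport becomes expression-decoupled: constant activity,
    # expression induced only by an unrelated carbon source
    decoupled_set <- "rht1_like"
    induction$rht1_like <- stats::setNames(fold, "glucomannan")
  }
  # background genes: seeded two-condition induction, no activity on the
  # assayed sugars; one constitutive and one never-induced gene give
  # constant expression rows downstream
  induction <- withr::with_seed(seed, {
    for (g in bg)
      induction[[g]] <- stats::setNames(rep(fold, 2),
                                        sample(setdiff(conds, "no_carbon"), 2))
    induction
  })
  basal <- stats::setNames(rep(1, length(transporters)), transporters)
  basal["sut15_like"] <- 8     # constitutively high
  basal["ncu07054_like"] <- 0.05  # weak in all conditions
  transportome_spec(
    activity = A, conditions = conds, induction = induction,
    basal_expression = basal, ccr_condition = "sucrose", ccr_factor = 0.2,
    ccr_transporters = setdiff(transporters,
                               c("glt1_like", "sut15_like", "ncu07054_like")),
    decoupled = decoupled_set,
    decoupled_activity = if (length(decoupled_set)) 5 else NULL,
    constitutive = c("sut15_like", "ncu07054_like"),
    noise_cv = noise_cv, seed = seed)
}

#' Minimal two-transporter redundancy scenario
#'
#' One sugar carried equally (activity 0.5 each) by two transporters with
#' disjoint induction sets. Because observed uptake is the sum of both
#' contributions, neither transporter's expression correlates perfectly
#' with uptake, while the summed expression does — the quantitative form of
#' the dilution of single-gene correlations under functional redundancy.
#'
#' @param noise_cv Observation noise CV (default 0).
#' @param seed Integer seed.
#' @param fold Fold induction (default 20).
#' @return A `transportome_spec` with transporters `tA`, `tB` and sugar
#'   `disacch`.
#' @export
preset_redundant_pair <- function(noise_cv = 0, seed = 1, fold = 20) {
  A <- matrix(c(0.5, 0.5), 2, 1,
              dimnames = list(c("tA", "tB"), "disacch"))
  transportome_spec(
    activity = A, conditions = DEFAULT_CONDITIONS,
    induction = list(tA = stats::setNames(fold, "cellulose"),
                     tB = stats::setNames(fold, "xylan")),
    basal_expression = 1, ccr_condition = NULL,
    noise_cv = noise_cv, seed = seed)
}

#' Write all simulated inputs of a truth object to disk
#'
#' Emits the expression matrix (TSV), assay records (long CSV), the
#' noise-free and observed uptake matrices (TSV), and the assignment shares
#' (JSON) under `outdir`.
#'
#' @param truth A `transportome_truth`.
#' @param outdir Output directory (created if missing).
#' @param assays Optional list of `uptake_assay` from
#'   [simulate_uptake_assays()]; generated with defaults when `NULL`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_inputs <- function(truth, outdir, assays = NULL) {
  stopifnot(inherits(truth, "transportome_truth"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(outdir, "expression.tsv"),
             assays = file.path(outdir, "assays.csv"),
             uptake_true = file.path(outdir, "uptake_true.tsv"),
             uptake_observed = file.path(outdir, "uptake_observed.tsv"),
             assignment = file.path(outdir, "assignment.json"))
  write_expression_tsv(truth$expression, paths[["expression"]])
  if (is.null(assays))
    assays <- simulate_uptake_assays(truth, seed = truth$spec$seed)
  write_assays_csv(assays, paths[["assays"]])
  write_expression_tsv(truth$uptake_true, paths[["uptake_true"]])
  write_expression_tsv(truth$uptake_observed, paths[["uptake_observed"]])
  jsonlite::write_json(lapply(truth$assignment, as.list),
                       paths[["assignment"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
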