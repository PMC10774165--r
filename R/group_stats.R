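# Group-comparison decision procedure for replicate growth/uptake data:
# Shapiro-Wilk normality gate, then Student t or Mann-Whitney U for two
# groups, one-way ANOVA with Tukey HSD and a compact letter display for
# three or more.

#' Two-group comparison with normality gating
#'
#' Each group is first tested for normality (Shapiro-Wilk). If both groups
#' are compatible with normality at `alpha`, a two-tailed equal-variance
#' Student t-test is used; otherwise a Mann-Whitney U test (exact when the
#' combined n is at most 20 and there are no ties, normal approximation
#' with continuity and tie correction otherwise). Significance stars follow
#' the usual convention (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param a,b Numeric measurement vectors, each n >= 3.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return List with `normality_p` (named, per group), `test_used`
#'   (`"t"` or `"mann_whitney"`), `statistic`, `p`, `stars`.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs n >= 3")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(normality_p = c(a = NA_real_, b = NA_real_),
                test_used = "t", statistic = 0, p = 1, stars = "ns"))
  shap <- function(x) {
    if (stats::var(x) == 0) return(NA_real_)   # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  pa <- shap(a); pb <- shap(b)
  normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  if (normal) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_used = "t", statistic = unname(ht$statistic),
                p = ht$p.value)
  } else {
    n_tot <- length(a) + length(b)
    ties <- anyDuplicated(c(a, b)) > 0L
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = n_tot <= 20 && !ties,
                         correct = TRUE))
    res <- list(test_used = "mann_whitney",
                statistic = unname(ht$statistic), p = ht$p.value)
  }
  c(list(normality_p = c(a = pa, b = pb)), res,
    list(stars = stars_for_p(res$p)))
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA across three or more groups, runs Tukey's honest
#' significant difference test on all pairs, and assigns letters by the
#' insert-and-absorb algorithm so that two groups share a letter exactly
#' when they are not significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors, or a data frame with
#'   columns `group` and `value`. At least 3 groups, each n >= 3.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `anova_p`, `tukey` (data frame of pairwise adjusted
#'   p-values) and `letters` (named character vector group -> letters).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 3L)
    stop("need >= 3 groups (use compare_two_groups for two)")
  if (any(vapply(groups, length, 0L) < 3L))
    stop("each group needs n >= 3")
  gnames <- names(groups) %||% paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(gnames, vapply(groups, length, 0L)), levels = gnames))
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(group1 = pairs[, 1L], group2 = pairs[, 2L],
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  sig <- tukey[!is.na(tukey$p_adj) & tukey$p_adj < alpha, , drop = FALSE]
  letters_map <- letter_display(gnames, sig)
  list(anova_p = anova_p, tukey = tukey, letters = letters_map)
}

# insert-and-absorb compact letter display: start with one column holding
# all groups; for every significant pair split each column containing both;
# absorb columns that are subsets of others; label columns a, b, c, ...
letter_display <- function(gnames, sig_pairs) {
  cols <- list(gnames)
  if (nrow(sig_pairs) > 0) for (k in seq_len(nrow(sig_pairs))) {
    g1 <- sig_pairs$group1[k]; g2 <- sig_pairs$group2[k]
    newcols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        newcols <- c(newcols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else newcols <- c(newcols, list(col))
    }
    # absorb: drop any column contained in another
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) for (j in seq_along(newcols)) {
      if (i != j && keep[i] && keep[j] &&
          all(newcols[[i]] %in% newcols[[j]]) &&
          (length(newcols[[i]]) < length(newcols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    cols <- unique(newcols[keep])
  }
  # order columns by the first group they contain, then letter them
  first_idx <- vapply(cols, function(col) min(match(col, gnames)), 0)
  cols <- cols[order(first_idx)]
  out <- stats::setNames(rep("", length(gnames)), gnames)
  for (i in seq_along(cols))
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}
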