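# Core inference: fuse uptake-rate rows with expression rows over matched
# induction conditions, cluster with Pearson-correlation distance, and rank
# transporter candidates per sugar.

#' Pearson correlation with constant-profile sentinel
#'
#' Standard product-moment correlation. If either profile is constant the
#' correlation is undefined and `NA` is returned (callers translate this to
#' distance 1 and flag the pair rather than dropping it).
#'
#' @param x,y Numeric profiles of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` for constant input.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("profiles must have length >= 3")
  if (is_constant_row(x) || is_constant_row(y)) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Fuse uptake and expression profiles over shared conditions
#'
#' Restricts both matrices to their shared induction conditions (ordered as
#' in the uptake matrix), applies the same transform to each block
#' independently (log2 with pseudocount, then per-row z-scoring), and stacks
#' sugar rows on top of gene rows with role tags. Requires at least 3 shared
#' conditions.
#'
#' @param uptake An `uptake_matrix` or plain sugars x conditions matrix.
#' @param expr Expression matrix, genes x conditions.
#' @param log2_transform Apply [log_transform()] first (default TRUE).
#' @param pseudocount Pseudocount for the log transform.
#' @param normalize `"zscore"` (default; per-row standardization) or
#'   `"none"`. Pearson similarity is unaffected by the choice, but exported
#'   matrices are not.
#' @return Object of class `joint_profile`: list with `values` (matrix),
#'   `roles` (`"sugar"`/`"gene"` per row), `conditions`, `constant_rows`.
#' @export
build_joint_profile <- function(uptake, expr, log2_transform = TRUE,
                                pseudocount = 1,
                                normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  up <- if (inherits(uptake, "uptake_matrix")) uptake$rates else uptake
  check_numeric_matrix(up, "uptake matrix")
  check_numeric_matrix(expr, "expression matrix")
  shared <- intersect(colnames(up), colnames(expr))
  shared <- colnames(up)[colnames(up) %in% shared]   # uptake order
  if (length(shared) < 3L)
    stop("need >= 3 shared conditions; uptake has {",
         paste(colnames(up), collapse = ", "), "}, expression has {",
         paste(colnames(expr), collapse = ", "), "}")
  up <- up[, shared, drop = FALSE]
  ex <- expr[, shared, drop = FALSE]
  if (any(is.na(up))) stop("uptake matrix has missing cells for shared conditions")
  transform_block <- function(m) {
    if (log2_transform) m <- log_transform(m, pseudocount)
    if (normalize == "zscore") standardize_rows(m)
    else structure(m, constant_rows = rownames(m)[apply(m, 1, is_constant_row)])
  }
  upt <- transform_block(up)
  ext <- transform_block(ex)
  labels <- c(rownames(up), rownames(ex))
  roles <- c(rep("sugar", nrow(up)), rep("gene", nrow(ex)))
  if (anyDuplicated(paste(roles, labels)))
    stop("duplicate row labels within a role")
  values <- rbind(upt, ext)
  rownames(values) <- labels
  structure(list(values = values, roles = roles, conditions = shared,
                 constant_rows = c(attr(upt, "constant_rows"),
                                   attr(ext, "constant_rows"))),
            class = "joint_profile")
}

#' @export
print.joint_profile <- function(x, ...) {
  cat("joint profile:", sum(x$roles == "sugar"), "sugars +",
      sum(x$roles == "gene"), "genes x", length(x$conditions), "conditions\n")
  if (length(x$constant_rows))
    cat("constant rows flagged:", paste(x$constant_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Pearson-correlation distance matrix of a joint profile
#'
#' `d(i, j) = 1 - r(i, j)`, symmetric, zero diagonal, bounded in `[0, 2]`.
#' Pairs involving a constant row (undefined r) get `d = 1`, equivalent to
#' treating r as 0, and the rows are flagged rather than dropped.
#'
#' @param jp A `joint_profile` (or plain matrix of row profiles).
#' @return Symmetric numeric matrix with attribute `constant_rows`.
#' @export
correlation_distance_matrix <- function(jp) {
  m <- if (inherits(jp, "joint_profile")) jp$values else jp
  r <- suppressWarnings(stats::cor(t(m), method = "pearson"))
  const <- apply(m, 1L, is_constant_row)
  r[const, ] <- 0
  r[, const] <- 0
  d <- 1 - r
  diag(d) <- 0
  d <- (d + t(d)) / 2
  attr(d, "constant_rows") <- rownames(m)[const]
  d
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Average (UPGMA), complete, or single linkage on a symmetric
#' dissimilarity. Average linkage defines the inter-cluster distance as the
#' unweighted mean over all cross pairs of the original dissimilarities.
#' When several pairs attain the minimal distance, the lexicographically
#' smallest index pair (by current cluster creation order) is merged, making
#' the output bit-reproducible across platforms.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`) with labels.
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return A standard [stats::hclust] object (merge, height, order, labels),
#'   usable with `cutree`, `plot`, `as.dendrogram`.
#' @export
average_linkage_cluster <- function(d, linkage = c("average", "complete",
                                                   "single")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity must be symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to cluster")
  labels <- rownames(d) %||% as.character(seq_len(n))
  D <- unname(d)
  size <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (ii in seq_along(act)) {
      i <- act[ii]
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        j <- act[jj]
        if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- bestd
    # Lance-Williams update into slot i; slot j retires
    for (k in act) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- switch(linkage,
        average = (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j]),
        complete = max(D[i, k], D[j, k]),
        single = min(D[i, k], D[j, k]))
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  if (any(diff(height) < -1e-10))
    stop("non-monotone merge heights: dissimilarity not metric-like")
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge), labels = labels,
                       method = linkage,
                       call = match.call(), dist.method = "1 - pearson"),
                  class = "hclust")
  hc
}

# leaf order for plotting: left-to-right traversal of the merge tree
hclust_order <- function(merge) {
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram into flat clusters
#'
#' Exactly one of `k` (number of clusters) or `h` (height) must be given.
#' Cluster ids are renumbered by first appearance along the dendrogram leaf
#' order, so cluster 1 is the leftmost.
#'
#' @param dend An `hclust` object from [average_linkage_cluster()].
#' @param k Number of clusters.
#' @param h Cut height.
#' @return Named integer vector label -> cluster id.
#' @export
cut_clusters <- function(dend, k = NULL, h = NULL) {
  if (!is.null(k) && !is.null(h)) stop("give either k or h, not both")
  if (is.null(k) && is.null(h)) stop("give one of k or h")
  cl <- stats::cutree(dend, k = k, h = h)
  first <- cl[dend$labels[dend$order]]
  remap <- stats::setNames(seq_along(unique(first)), unique(first))
  out <- remap[as.character(cl)]
  names(out) <- names(cl)
  storage.mode(out) <- "integer"
  out
}

#' Rank transporter candidates per sugar
#'
#' For each sugar row of the joint profile, all gene rows are sorted by
#' descending Pearson correlation with the sugar's profile. Genes with a
#' constant (flagged) profile have undefined correlation; they are reported
#' with `r = NA` and ranked last, never dropped. `same_cluster` records
#' co-membership at the `k`-cluster cut of the dendrogram.
#'
#' @param jp A `joint_profile` with at least one sugar and one gene row.
#' @param dend Optional `hclust` of the joint profile (for `same_cluster`).
#' @param k Number of clusters for the cut (default 5).
#' @return Named list (by sugar) of data frames with columns `gene`, `r`,
#'   `distance` (`1 - r`), `same_cluster`, `rank`.
#' @export
rank_candidates <- function(jp, dend = NULL, k = 5) {
  stopifnot(inherits(jp, "joint_profile"))
  sugars <- rownames(jp$values)[jp$roles == "sugar"]
  genes <- rownames(jp$values)[jp$roles == "gene"]
  if (length(sugars) == 0L || length(genes) == 0L)
    stop("joint profile needs >= 1 sugar and >= 1 gene row")
  cl <- if (!is.null(dend)) cut_clusters(dend, k = k) else NULL
  out <- lapply(sugars, function(s) {
    sp <- jp$values[s, ]
    r <- vapply(genes, function(g) pearson_cor(sp, jp$values[g, ]), 0)
    ord <- order(-r, na.last = TRUE)   # stable: ties keep gene order
    dist <- ifelse(is.na(r[ord]), 1, 1 - r[ord])  # constant rows: r treated as 0
    df <- data.frame(gene = genes[ord], r = r[ord], distance = dist,
                     same_cluster = if (is.null(cl)) NA else
                       unname(cl[genes[ord]] == cl[s]),
                     rank = seq_along(genes), stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
  names(out) <- sugars
  out
}
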