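# Independent oracles used across tests.

# Brute-force agglomerative clustering: at every step the inter-cluster
# distance is recomputed by a full re-scan over all original cross pairs
# (no Lance-Williams updates). Same tie-break as the implementation:
# lexicographically smallest pair by cluster creation order.
brute_upgma <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))      # original indices per active cluster
  ids <- -seq_len(n)                  # hclust convention
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- NULL; bestd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      cross <- d[members[[i]], members[[j]], drop = FALSE]
      dij <- switch(linkage, average = mean(cross), complete = max(cross),
                    single = min(cross))
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- bestd
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    ids[i] <- step
    ids <- ids[-j]
  }
  list(merge = merge, height = height)
}

# random symmetric dissimilarity with zero diagonal
random_dissimilarity <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("x", seq_len(n)), paste0("x", seq_len(n)))
  m
}

# random binary tree with U(0.1, 2) branch lengths and its additive
# tip-to-tip distance matrix
random_additive_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# four-taxon alignment in which every column individually supports the
# AB|CD split (or is constant), so any column resample yields the same tree
unanimous_alignment <- function() {
  col <- function(x) matrix(x, 4)
  M <- cbind(matrix(rep(c("A", "A", "G", "G"), 30), 4),
             matrix(rep(c("A", "C", "A", "A"), 5), 4),
             matrix(rep(c("A", "A", "A", "C"), 5), 4),
             matrix(rep(c("A", "A", "C", "A"), 5), 4),
             matrix(rep(c("C", "A", "A", "A"), 5), 4))
  stats::setNames(apply(M, 1, paste, collapse = ""), c("A", "B", "C", "D"))
}

top1_accuracy <- function(truth, rankings) {
  top1 <- vapply(names(rankings), function(s) rankings[[s]]$gene[1L], "")
  dominant <- vapply(names(truth$assignment), function(s)
    names(which.max(truth$assignment[[s]])), "")
  mean(top1 == dominant[names(top1)])
}
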