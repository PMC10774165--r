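# Joint-profile construction, correlation distance, average linkage with
# deterministic tie-break, cluster cuts, candidate ranking.

small_joint <- function() {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   5, 4, 3, 2, 1,
                   2, 2, 2, 2, 2), 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"),
                                 paste0("c", 1:5)))
  up <- matrix(c(2, 4, 6, 8, 10), 1,
               dimnames = list("sug", paste0("c", 1:5)))
  build_joint_profile(up, expr, log2_transform = FALSE)
}

test_that("pearson handles the hand examples and degenerate input", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_cor(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_cor(1:3, 1:4), "length")
  expect_error(pearson_cor(1:2, 1:2), ">= 3")
})

test_that("joint profile restricts to shared conditions in uptake order", {
  expr <- matrix(1:12, 2, 6,
                 dimnames = list(c("g1", "g2"), paste0("c", 1:6)))
  up <- matrix(c(1, 5, 2, 9), 1, 4,
               dimnames = list("s1", c("c4", "c2", "c6", "c1")))
  jp <- build_joint_profile(up, expr, log2_transform = FALSE)
  expect_equal(jp$conditions, c("c4", "c2", "c6", "c1"))
  expect_equal(rownames(jp$values), c("s1", "g1", "g2"))
  expect_equal(jp$roles, c("sugar", "gene", "gene"))
  colnames(up) <- c("x1", "x2", "x3", "x4")
  expect_error(build_joint_profile(up, expr), "shared conditions")
})

test_that("identical pre-transform rows stay identical post-transform", {
  expr <- matrix(c(1, 4, 9, 2, 3, 7), 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("c", 1:3)))
  up <- matrix(c(1, 4, 9), 1, dimnames = list("s1", paste0("c", 1:3)))
  jp <- build_joint_profile(up, expr)
  expect_equal(unname(jp$values["s1", ]), unname(jp$values["g1", ]))
})

test_that("correlation distance is bounded, symmetric, and flags constants", {
  jp <- small_joint()
  d <- correlation_distance_matrix(jp)
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  expect_equal(d, t(d))
  expect_equal(unname(d["sug", "gA"]), 0)        # proportional rows
  expect_equal(unname(d["sug", "gB"]), 2)        # anticorrelated
  expect_equal(unname(d["sug", "gC"]), 1)        # constant row convention
  expect_true("gC" %in% attr(d, "constant_rows"))
})

test_that("average linkage reproduces hand-traced merges", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- average_linkage_cluster(d)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_equal(hc$merge[1L, ], c(-1L, -2L))
  # identical pair merges first at height 0
  d2 <- d; d2["a", "b"] <- d2["b", "a"] <- 0
  hc2 <- average_linkage_cluster(d2)
  expect_equal(hc2$height[1L], 0)
})

test_that("average linkage equals the brute-force re-scan oracle", {
  set.seed(11)
  for (i in 1:100) {
    d <- random_dissimilarity(8)
    hc <- average_linkage_cluster(d)
    oracle <- brute_upgma(d)
    expect_identical(hc$merge, oracle$merge)
    expect_equal(hc$height, oracle$height, tolerance = 1e-12)
  }
})

test_that("complete and single linkage match their brute-force variants", {
  set.seed(12)
  for (lk in c("complete", "single")) {
    d <- random_dissimilarity(7)
    hc <- average_linkage_cluster(d, linkage = lk)
    oracle <- brute_upgma(d, linkage = lk)
    expect_identical(hc$merge, oracle$merge)
    expect_equal(hc$height, oracle$height, tolerance = 1e-12)
  }
})

test_that("heights agree with stats::hclust average linkage", {
  set.seed(13)
  d <- random_dissimilarity(10)
  expect_equal(average_linkage_cluster(d)$height,
               stats::hclust(stats::as.dist(d), "average")$height,
               tolerance = 1e-12)
})

test_that("cluster cuts behave at the extremes and reject double input", {
  set.seed(14)
  d <- random_dissimilarity(6)
  hc <- average_linkage_cluster(d)
  expect_equal(length(unique(cut_clusters(hc, k = 6))), 6L)
  expect_equal(unname(cut_clusters(hc, k = 1)), rep(1L, 6))
  expect_error(cut_clusters(hc, k = 2, h = 0.5), "not both")
  expect_error(cut_clusters(hc), "one of")
  # ids numbered by first appearance along the dendrogram
  cl <- cut_clusters(hc, k = 3)
  leaf_order <- hc$labels[hc$order]
  expect_equal(unique(unname(cl[leaf_order])), 1:3)
})

test_that("candidate ranking sorts by r and ranks constant genes last", {
  jp <- small_joint()
  hc <- average_linkage_cluster(correlation_distance_matrix(jp))
  rk <- rank_candidates(jp, hc, k = 2)
  expect_equal(rk$sug$gene, c("gA", "gB", "gC"))
  expect_equal(rk$sug$r[1L], 1)
  expect_true(is.na(rk$sug$r[3L]))
  expect_equal(rk$sug$distance[3L], 1)
  expect_equal(rk$sug$rank, 1:3)
})

test_that("ranking is invariant to per-row affine rescaling of inputs", {
  tt <- simulate_transportome(preset_neurospora_like(noise_cv = 0, seed = 5))
  jp1 <- build_joint_profile(tt$uptake_observed, tt$expression,
                             log2_transform = FALSE)
  scale_rows <- function(m, f, o) m * f + o
  set.seed(6)
  f <- runif(nrow(tt$expression), 0.5, 3)
  jp2 <- build_joint_profile(tt$uptake_observed,
                             tt$expression * f + 0.7,
                             log2_transform = FALSE)
  rk1 <- rank_candidates(jp1)
  rk2 <- rank_candidates(jp2)
  for (s in names(rk1)) {
    # per-gene correlations are invariant; the printed order may permute
    # exact ties among background genes, so compare r by gene, not by rank
    r1 <- stats::setNames(rk1[[s]]$r, rk1[[s]]$gene)
    r2 <- stats::setNames(rk2[[s]]$r, rk2[[s]]$gene)
    g <- sort(names(r1))
    expect_equal(r1[g], r2[g], tolerance = 1e-9)
    expect_equal(rk1[[s]]$gene[1L], rk2[[s]]$gene[1L])
  }
})

test_that("redundant transporters dilute single-gene correlations", {
  tt <- simulate_transportome(preset_redundant_pair())
  u <- tt$uptake_true["disacch", ]
  rA <- pearson_cor(u, tt$expression["tA", ])
  rB <- pearson_cor(u, tt$expression["tB", ])
  expect_lt(rA, 1)
  expect_lt(rB, 1)
  expect_equal(pearson_cor(u, tt$expression["tA", ] + tt$expression["tB", ]),
               1, tolerance = 1e-9)
})

test_that("sugars co-cluster with their dominant transporter at the preset cut", {
  tt <- simulate_transportome(preset_neurospora_like(noise_cv = 0, seed = 3))
  jp <- build_joint_profile(tt$uptake_observed, tt$expression)
  hc <- average_linkage_cluster(correlation_distance_matrix(jp))
  rk <- rank_candidates(jp, hc, k = 5)
  cl <- cut_clusters(hc, k = 5)
  for (s in names(rk)) {
    dominant <- names(which.max(tt$assignment[[s]]))
    expect_true(rk[[s]]$gene[1L] %in% names(tt$assignment[[s]]))
    expect_equal(unname(cl[s]), unname(cl[dominant]))
  }
})
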