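# Poisson distances with pairwise deletion, neighbor joining, bootstrap
# support, clade assignment, Newick round trips.

test_that("poisson distance: closed form, pairwise deletion, saturation cap", {
  expect_equal(poisson_distance("ACDEF", "ACDEF")$d, 0)
  # 2 mismatches over 10 compared sites
  pd <- poisson_distance("AAAAAAAAAA", "AAAAAAAACC")
  expect_equal(pd$p, 0.2)
  expect_equal(pd$d, -log(0.8))
  # gapped pair: compared sites are 1, 2, 4 only
  pd2 <- poisson_distance("ACDE-", "AC-EF")
  expect_equal(pd2$n_sites, 3L)
  expect_equal(pd2$d, 0)
  # X treated as missing like a gap
  expect_equal(poisson_distance("AXC", "AAC")$n_sites, 2L)
  # saturated pair capped and flagged
  pd3 <- poisson_distance("AAAA", "CCCC", p_cap = 0.99)
  expect_true(pd3$capped)
  expect_equal(pd3$d, -log(0.01))
  expect_error(poisson_distance("--", "AA"), "no overlapping sites")
  # monotone in p and ~ p for small p
  p_small <- 0.02
  d_small <- -log(1 - p_small)
  expect_lt(abs(d_small - p_small), p_small^2)
})

test_that("distance matrix is symmetric with per-pair site counts", {
  aln <- c(a = "ACDEF", b = "ACDEF", c = "AC-EF")
  d <- poisson_distance_matrix(aln)
  expect_equal(d, t(d))
  expect_equal(unname(d["a", "b"]), 0)
  ns <- attr(d, "n_sites")
  expect_equal(unname(ns["a", "b"]), 5L)
  expect_equal(unname(ns["a", "c"]), 4L)
})

test_that("NJ solves the three-taxon star exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(bl[c("a", "b", "c")], c(a = 0.5, b = 1.5, c = 2.5))
})

test_that("NJ recovers the known four-taxon additive tree", {
  # built from ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  # AB|CD is the (single) internal split; canonical key is the side not
  # containing the alphabetically first leaf
  key <- transportome:::tree_bipartitions(tr)
  expect_equal(key, "C|D")
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ is consistent on random additive trees and matches ape::nj", {
  set.seed(21)
  for (i in 1:30) {
    ref <- random_additive_tree(sample(4:10, 1))
    tr <- neighbor_joining(ref$d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref$tree)), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(ref$d),
                                                colnames(ref$d)] - ref$d)),
              1e-9)
    ape_tr <- ape::nj(stats::as.dist(ref$d))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape_tr)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative branch estimates are clamped to zero, never negative", {
  d <- matrix(c(0, 5, 9, 10,
                5, 0, 10, 9,
                9, 10, 0, 8,
                10, 9, 8, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)   # non-additive: can push a length negative
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap: unanimous alignment gives support 1, seeded, bounded", {
  aln <- unanimous_alignment()
  bt <- bootstrap_support(aln, n_reps = 200, seed = 3)
  sup <- attr(bt, "support")
  expect_equal(unname(sup), rep(1, length(sup)))
  expect_equal(attr(bt, "n_effective_reps"), 200L)
  # single replicate: supports are 0 or 1
  bt1 <- bootstrap_support(aln, n_reps = 1, seed = 5)
  expect_true(all(attr(bt1, "support") %in% c(0, 1)))
  # determinism and bounds on a noisy alignment
  tr <- ape::rtree(6)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
  aln2 <- simulate_alignment(tr, 120, seed = 8)
  b1 <- bootstrap_support(aln2, n_reps = 100, seed = 9)
  b2 <- bootstrap_support(aln2, n_reps = 100, seed = 9)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_true(all(attr(b1, "support") >= 0 & attr(b1, "support") <= 1))
})

test_that("simulated-alignment distances approximate true path lengths", {
  set.seed(31)
  tr <- ape::rtree(5)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.3)
  aln <- simulate_alignment(tr, 20000, seed = 13)
  d <- poisson_distance_matrix(aln)
  true_d <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  # Poisson correction understates the 20-state distance slightly; compare
  # on the p scale where the closed form is exact
  p_obs <- 1 - exp(-d)
  p_true <- (19 / 20) * (1 - exp(-20 * true_d / 19))
  off <- abs(p_obs - p_true)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_true(all(off[upper.tri(off)] < 4 * se[upper.tri(se)] + 1e-12))
})

test_that("clade assignment places queries in pure subtrees, else unplaced", {
  # two well-separated reference clades with one query inside each and one
  # query on the backbone
  txt <- "(((r1:0.1,r2:0.1):0.1,q1:0.1):1,((r3:0.1,r4:0.1):0.1,q2:0.1):1,q3:2);"
  tr <- ape::read.tree(text = txt)
  refs <- c(r1 = "V", r2 = "V", r3 = "VII", r4 = "VII")
  out <- assign_clades(tr, refs)
  expect_equal(out[["q1"]], "V")
  expect_equal(out[["q2"]], "VII")
  expect_equal(out[["q3"]], "unplaced")
  # a threshold above 1 can never be met
  out2 <- assign_clades(tr, refs, threshold = 1.01)
  expect_true(all(out2 == "unplaced"))
  expect_error(assign_clades(tr, c(r1 = "V", r2 = "V")), ">= 2 clades")
})

test_that("Newick round trip is idempotent and preserves supports", {
  aln <- unanimous_alignment()
  bt <- bootstrap_support(aln, n_reps = 50, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".nwk")
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, p1)
  t2 <- read_newick(p1)
  write_newick(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_setequal(t2$tip.label, names(aln))
})

test_that("aligned FASTA reader handles wrapping and case, writer round-trips", {
  aln <- c(seqA = "MKTAYIAKQR", seqB = "MKTA-IAKQR")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, path)
  expect_equal(read_fasta_alignment(path), aln)
  # wrapped + lower case input
  writeLines(c(">s1", "mkta", "yiak", ">s2", "MKTA", "-IAK"), path)
  back <- read_fasta_alignment(path)
  expect_equal(unname(back), c("MKTAYIAK", "MKTA-IAK"))
  writeLines(c(">s1", "MKT", ">s2", "MKTA"), path)
  expect_error(read_fasta_alignment(path), "same length")
})
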