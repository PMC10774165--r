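# Synthetic transportome generator: additive model, noise, determinism,
# and round trips through the downstream reducers.

spec_identity <- function(noise_cv = 0, seed = 1) {
  n <- 5L
  A <- diag(n)
  dimnames(A) <- list(paste0("t", 1:n), paste0("s", 1:n))
  conds <- c("no_carbon", "sucrose", "c1", "c2", "c3", "c4", "c5")
  ind <- stats::setNames(lapply(1:n, function(i)
    stats::setNames(10, paste0("c", i))), paste0("t", 1:n))
  transportome_spec(activity = A, conditions = conds, induction = ind,
                    ccr_condition = "sucrose", noise_cv = noise_cv,
                    seed = seed)
}

test_that("identity activity makes uptake rows equal expression rows", {
  tt <- simulate_transportome(spec_identity())
  expect_equal(unname(tt$uptake_true), unname(tt$expression))
  expect_equal(tt$uptake_observed, tt$uptake_true)  # noise_cv = 0
})

test_that("two half-activity transporters average their expression rows", {
  A <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(c("t1", "t2"), "s"))
  conds <- c("a", "b", "c", "d")
  ind <- list(t1 = c(b = 8), t2 = c(b = 8))   # identical induction
  sp <- transportome_spec(A, conditions = conds, induction = ind,
                          ccr_condition = NULL, noise_cv = 0)
  tt <- simulate_transportome(sp)
  expect_equal(tt$uptake_true["s", ],
               colMeans(tt$expression))
})

test_that("same spec and seed reproduce bit-identical output", {
  t1 <- simulate_transportome(spec_identity(noise_cv = 0.3, seed = 42))
  t2 <- simulate_transportome(spec_identity(noise_cv = 0.3, seed = 42))
  expect_identical(t1, t2)
  t3 <- simulate_transportome(spec_identity(noise_cv = 0.3, seed = 43))
  expect_false(identical(t1$uptake_observed, t3$uptake_observed))
})

test_that("orphan sugars (all-zero activity column) are rejected", {
  A <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  expect_error(transportome_spec(A, conditions = c("a", "b", "c")),
               "orphan sugar")
})

test_that("additivity and monotonicity of the uptake model", {
  base <- spec_identity()
  A1 <- base$activity
  set.seed(7)
  A2 <- matrix(runif(length(A1)), nrow(A1), dimnames = dimnames(A1))
  mk <- function(A) {
    sp <- base; sp$activity <- A
    simulate_transportome(sp)$uptake_true
  }
  expect_equal(mk(A1 + A2), mk(A1) + mk(A2))
  # raising one activity entry never decreases any uptake value
  A3 <- A1; A3[2, 3] <- A3[2, 3] + 1.5
  expect_true(all(mk(A3) >= mk(A1)))
})

test_that("assignment shares are nonnegative and sum to one per sugar", {
  tt <- simulate_transportome(preset_neurospora_like(seed = 3))
  for (s in names(tt$assignment)) {
    sh <- tt$assignment[[s]]
    expect_true(all(sh > 0))
    expect_equal(sum(sh), 1, tolerance = 1e-9)
  }
})

test_that("simulated assays invert to the true rates and flag depletion", {
  tt <- simulate_transportome(spec_identity())
  assays <- simulate_uptake_assays(tt, c0_uM = 5000, seed = 2)
  um <- build_uptake_matrix(assays)
  expect_equal(um$rates[rownames(tt$uptake_true), colnames(tt$uptake_true)],
               tt$uptake_true, tolerance = 1e-9)
  expect_equal(unique(as.vector(um$n_replicates)), 3L)
  # hand-derived depletion: rate 6, 3 mL, 2 mg, c0 100 -> C(15) = 40
  A <- matrix(1, 1, 1, dimnames = list("t", "s"))
  sp <- transportome_spec(A, conditions = c("a", "b", "c"),
                          induction = list(t = c(a = 6)),
                          basal_expression = 1, ccr_condition = NULL,
                          noise_cv = 0)
  tt2 <- simulate_transportome(sp)
  expect_equal(unname(tt2$uptake_true["s", "a"]), 6)
  a <- simulate_uptake_assays(tt2, volume_L = 0.003, biomass_mg = 2,
                              c0_uM = 100, n_replicates = 1, seed = 1)
  conc <- vapply(a, function(x) x$conc_uM[2L], 0)
  names(conc) <- vapply(a, function(x) x$condition, "")
  expect_equal(unname(conc["a"]), 40)
  expect_equal(unname(conc["b"]), 90)   # basal rate 1 -> 10 uM depleted
  # too-fast uptake floors at zero and is flagged
  sp$induction$t <- c(a = 50)
  a2 <- simulate_uptake_assays(simulate_transportome(sp), c0_uM = 100,
                               n_replicates = 1, seed = 1)
  dep <- attr(a2, "depleted")
  expect_true(nrow(dep) >= 1 && "a" %in% dep$condition)
  expect_true(all(vapply(a2, function(x) all(x$conc_uM >= 0), TRUE)))
})

test_that("alignment simulator honours branch lengths, gaps and seeds", {
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  expect_equal(length(unique(simulate_alignment(tr0, 50, seed = 1))), 1L)
  tr <- ape::read.tree(text = "(A:0.2,B:0.3);")
  expect_identical(simulate_alignment(tr, 100, seed = 5),
                   simulate_alignment(tr, 100, seed = 5))
  expect_error(simulate_alignment(tr, 0), "n_sites")
  ag <- simulate_alignment(tr, 500, seed = 2, gap_fraction = 0.2)
  gaps <- vapply(strsplit(ag, ""), function(v) mean(v == "-"), 0)
  expect_equal(unname(gaps), rep(0.2, 2), tolerance = 1e-9)
})

test_that("long two-taxon alignments approach the 20-state closed form", {
  # p -> (19/20) (1 - exp(-20 b / 19)) for path length b; Monte-Carlo check
  b <- 0.7
  tr <- ape::read.tree(text = "(A:0.3,B:0.4);")
  aln <- simulate_alignment(tr, 1e5, seed = 9)
  pd <- poisson_distance(aln[["A"]], aln[["B"]])
  expected <- (19 / 20) * (1 - exp(-20 * b / 19))
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(pd$p - expected), 4 * se)
})

test_that("qPCR simulator is exact at zero noise with triplicate structure", {
  q <- simulate_qpcr(3, true_fold = 16, seed = 1)
  expect_equal(ddct_fold_change(q)$fold_change, 16, tolerance = 1e-12)
  expect_equal(nrow(q), 2 * 3 * 2)   # 2 groups x 3 samples x target+reference
  expect_true(all(c("ct1", "ct2", "ct3") %in% names(q)))
  q1 <- simulate_qpcr(2, true_fold = 1, seed = 1)
  dct <- ddct_fold_change(q1)
  expect_equal(unname(dct$dct_mean["treatment"]),
               unname(dct$dct_mean["calibrator"]))
})

test_that("simulated input bundle round-trips through the file readers", {
  tt <- simulate_transportome(preset_neurospora_like(noise_cv = 0, seed = 2))
  out <- withr::local_tempdir()
  paths <- write_simulated_inputs(tt, out)
  expect_equal(read_expression_tsv(paths[["expression"]]), tt$expression)
  assays <- read_assays_csv(paths[["assays"]])
  expect_gt(length(assays), 0)
  expect_s3_class(assays[[1L]], "uptake_assay")
})
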