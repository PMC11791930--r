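# Monte Carlo reference-based consensus clustering.

test_that("consensus separates point masses and is a valid matrix", {
  x <- c(rep(0, 20), rep(10, 20))
  set.seed(30)
  cons <- consensus_cluster(x, k = 2, iterations = 40)
  within <- cons[1:20, 1:20]
  between <- cons[1:20, 21:40]
  expect_true(all(within[upper.tri(within)] == 1))
  expect_true(all(between == 0))
  expect_true(isSymmetric(cons))
  expect_true(all(diag(cons) == 1))
  expect_true(all(cons >= 0 & cons <= 1))
  expect_error(consensus_cluster(x, k = 41), "exceeds")
})

test_that("full resampling with deterministic linkage gives binary consensus", {
  set.seed(31)
  x <- rnorm(25)
  cons <- consensus_cluster(x, k = 3, iterations = 20, resample_fraction = 1)
  expect_true(all(cons %in% c(0, 1)))
})

test_that("PAC matches the explicit double-loop count", {
  all01 <- matrix(sample(c(0, 1), 64, TRUE), 8, 8)
  all01 <- (all01 + t(all01) > 0) * 1; diag(all01) <- 1
  expect_equal(pac_score(all01), 0)
  half <- matrix(0.5, 6, 6); diag(half) <- 1
  expect_equal(pac_score(half), 1)
  set.seed(32)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    cons <- matrix(runif(n * n), n, n)
    cons <- (cons + t(cons)) / 2; diag(cons) <- 1
    expect_equal(pac_score(cons), oracle_pac(cons))
    lo <- runif(1, 0, 0.4); hi <- runif(1, 0.6, 1)
    expect_equal(pac_score(cons, lo, hi), oracle_pac(cons, lo, hi))
  }
  expect_error(pac_score(matrix(1, 1, 1)), "1 x 1")
})

test_that("the reference null preserves moments but destroys structure", {
  set.seed(33)
  x <- matrix(c(rnorm(100, 0), rnorm(100, 6)), ncol = 1)
  ref <- prismms:::with_private_seed(1, simulate_reference(x))
  big <- prismms:::with_private_seed(2, {
    matrix(unlist(replicate(50, simulate_reference(x))), ncol = 1)
  })
  expect_equal(mean(big), mean(x), tolerance = 0.05)
  expect_equal(sd(big), sd(x), tolerance = 0.05)
  # bimodality gone: reference PAC at k = 2 far above real PAC
  set.seed(34)
  pac_real <- pac_score(consensus_cluster(x, 2, 30))
  pac_ref <- pac_score(consensus_cluster(ref, 2, 30))
  expect_gt(pac_ref, pac_real + 0.1)
  # multivariate path keeps the covariance scale
  set.seed(35)
  xm <- matrix(rnorm(300), 100, 3) %*% matrix(c(2, 1, 0, 0, 1, 0, 0, 0.5, 1), 3)
  refs <- prismms:::with_private_seed(3, {
    Reduce(`+`, replicate(200, cov(simulate_reference(xm)), simplify = FALSE)) / 200
  })
  expect_equal(refs, cov(xm), tolerance = 0.15)
  # deterministic under a fixed seed
  r1 <- prismms:::with_private_seed(7, simulate_reference(x))
  r2 <- prismms:::with_private_seed(7, simulate_reference(x))
  expect_identical(r1, r2)
})

test_that("k is recovered on planted mixtures and withheld on one Gaussian", {
  set.seed(36)
  x3 <- c(rnorm(40, 0, 0.5), rnorm(40, 6, 0.5), rnorm(40, 12, 0.5))
  r3 <- run_m3c(x3, max_k = 5, iterations = 40, ref_iterations = 100, seed = 1)
  expect_equal(r3$selected_k, 3L)
  expect_length(r3$assignments, 120L)
  expect_equal(length(unique(r3$assignments)), 3L)
  # planted partition recovered exactly
  truth <- rep(1:3, each = 40)
  expect_equal(length(unique(paste(truth, r3$assignments))), 3L)
})

test_that("results are deterministic and invariant to object order", {
  set.seed(37)
  x <- c(rnorm(30, 0), rnorm(30, 5))
  a <- run_m3c(x, max_k = 3, iterations = 25, ref_iterations = 40, seed = 5)
  b <- run_m3c(x, max_k = 3, iterations = 25, ref_iterations = 40, seed = 5)
  expect_identical(a$per_k, b$per_k)
  expect_identical(a$assignments, b$assignments)
  perm <- sample(length(x))
  c_ <- run_m3c(x[perm], max_k = 3, iterations = 25, ref_iterations = 40, seed = 5)
  expect_identical(c_$selected_k, a$selected_k)
  expect_identical(c_$per_k, a$per_k)
  expect_identical(c_$assignments, a$assignments[perm])
})

test_that("p-values carry the add-one floor and RCSI stays finite", {
  set.seed(38)
  x <- c(rnorm(25, 0, 0.3), rnorm(25, 9, 0.3))
  r <- run_m3c(x, max_k = 3, iterations = 25, ref_iterations = 40, seed = 2)
  expect_true(all(r$per_k$p_value >= 1 / 41))
  expect_true(all(is.finite(r$per_k$rcsi)))
  # with only 40 reference iterations p < 0.01 is unattainable
  expect_identical(r$selected_k, "homogeneous")
  r2 <- run_m3c(x, max_k = 3, iterations = 25, ref_iterations = 110, seed = 2)
  expect_equal(r2$selected_k, 2L)
})

test_that("false subcluster calls on a single Gaussian stay rare", {
  # a priori allowance: at most 3 of 25 seeded null runs may select k >= 2
  hits <- 0L
  for (s in 1:25) {
    x <- prismms:::with_private_seed(1000 + s, rnorm(40))
    r <- run_m3c(x, max_k = 2, iterations = 25, ref_iterations = 110, seed = s)
    if (!identical(r$selected_k, "homogeneous")) hits <- hits + 1L
  }
  expect_lte(hits, 3L)
})

test_that("majority vote across repeats is reported", {
  set.seed(39)
  x <- c(rnorm(50, 0, 0.5), rnorm(50, 8, 0.5))
  r <- run_m3c(x, max_k = 2, iterations = 20, ref_iterations = 110, seed = 3,
               repeats = 3)
  expect_equal(r$config$repeats, 3)
  expect_equal(r$selected_k, 2L)
})
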