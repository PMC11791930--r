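# Effect sizes, multiple-testing adjustment and volcano classification.

test_that("Cohen's D follows the mean-difference and pooled-sd conventions", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 2, 1)), 0)
  a <- rnorm(20, 0.5); b <- rnorm(20, -0.5)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(rep(c(0, 1), 10), rep(c(-1, 0), 10)), 1)  # unit-sd path
  # pooled-sd path equals the textbook formula
  set.seed(50)
  x <- rnorm(15, 1, 2); y <- rnorm(10, 0, 1)
  pooled <- sqrt((14 * var(x) + 9 * var(y)) / 23)
  expect_equal(cohens_d(x, y, assume_unit_sd = FALSE),
               (mean(x) - mean(y)) / pooled)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment matches the hand step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(51)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- runif(10)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("planted effects classify correctly and thresholds gate the classes", {
  set.seed(52)
  g1 <- matrix(rnorm(100 * 5), 100, 5); g2 <- matrix(rnorm(100 * 5), 100, 5)
  g1[, 2] <- g1[, 2] + 1          # planted up-feature, delta = 1 sd
  g2[, 4] <- g2[, 4] + 1          # planted down-feature
  vt <- volcano(g1, g2)
  expect_s3_class(vt, "prism_volcano")
  expect_equal(vt$class[2], "up")
  expect_equal(vt$class[4], "down")
  expect_true(all(vt$p_adj >= vt$p_raw))
  # class invariant: up <=> D > thr and p_adj < thr
  expect_equal(vt$class == "up", vt$cohens_d > 0.2 & vt$p_adj < 0.05)
  # threshold above max |D| silences everything
  vt2 <- volcano(g1, g2, d_threshold = max(abs(vt$cohens_d)) + 1)
  expect_true(all(vt2$class == "ns"))
  # swap group order: D flips sign, classes mirror
  vts <- volcano(g2, g1)
  expect_equal(vts$cohens_d, -vt$cohens_d)
  expect_equal(vts$class[2], "down")
  # column order invariance
  vtp <- volcano(g1[, 5:1], g2[, 5:1])
  expect_equal(vtp$cohens_d, rev(vt$cohens_d))
  expect_equal(vtp$class, rev(vt$class))
})

test_that("features constant in both groups are flagged untestable", {
  g1 <- cbind(rnorm(10), 7); g2 <- cbind(rnorm(10), 7)
  vt <- volcano(g1, g2)
  expect_true(vt$untestable[2])
  expect_equal(vt$class[2], "ns")
  expect_equal(vt$p_raw[2], 1)
})

test_that("permuted labels produce near-nominal raw and fewer BH hits", {
  set.seed(53)
  pool <- matrix(rnorm(200 * 40), 200, 40)
  raw_hits <- bh_hits <- 0
  for (i in 1:20) {
    idx <- sample(200, 100)
    vt <- volcano(pool[idx, ], pool[-idx, ])
    raw_hits <- raw_hits + mean(vt$p_raw < 0.05)
    bh_hits <- bh_hits + mean(vt$class != "ns")
  }
  expect_lt(abs(raw_hits / 20 - 0.05), 0.035)  # near-nominal raw rate
  expect_lt(bh_hits / 20, raw_hits / 20)       # BH strictly more conservative
})

test_that("pixel subsampling averages repeats and degenerates correctly", {
  set.seed(54)
  p1 <- matrix(rnorm(1000 * 4), 1000, 4); p1[, 1] <- p1[, 1] + 1
  p2 <- matrix(rnorm(1000 * 4), 1000, 4)
  # exactly n pixels: every repeat samples all of them
  one <- subsample_pixels(list(a = p1, b = p2), n_per_condition = 1000,
                          repeats = 3, seed = 9)
  direct <- volcano(p1, p2)
  expect_equal(one$cohens_d, direct$cohens_d, tolerance = 1e-12)
  expect_equal(one$p_adj, direct$p_adj, tolerance = 1e-12)
  # repeats = 1 equals a single volcano run on one subsample
  r1a <- subsample_pixels(list(a = p1, b = p2), 200, repeats = 1, seed = 10)
  r1b <- subsample_pixels(list(a = p1, b = p2), 200, repeats = 1, seed = 10)
  expect_equal(r1a, r1b)
  expect_equal(r1a$class[1], "up")
  # planted differential feature dominates the averaged effect sizes
  rs <- subsample_pixels(list(a = p1, b = p2), 300, repeats = 5, seed = 11)
  expect_true(abs(rs$cohens_d[1]) > max(abs(rs$cohens_d[-1])))
  expect_warning(
    subsample_pixels(list(a = p1[1:50, ], b = p2), 1000, repeats = 2, seed = 1),
    "sampling all")
})

test_that("trend concordance counts planted agreements", {
  mk <- function(classes) {
    out <- data.frame(mz = seq_along(classes), cohens_d = 0, p_raw = 0,
                      p_adj = 0, class = classes, untestable = FALSE)
    class(out) <- c("prism_volcano", "data.frame")
    out
  }
  t1 <- mk(c(rep("up", 6), rep("down", 5), rep("ns", 9)))
  flip <- c(rep("down", 6), rep("up", 5), rep("ns", 9))
  same <- marker_concordance(list(a = t1, b = t1))
  expect_equal(sum(same$concordant), 11)          # all non-ns agree
  opp <- marker_concordance(list(a = t1, b = mk(flip)))
  expect_equal(sum(opp$concordant), 0)
  # planted 11 concordant of 20
  t2 <- mk(c(rep("up", 6), rep("down", 5), rep("up", 9)))
  part <- marker_concordance(list(a = t1, b = t2))
  expect_equal(sum(part$concordant), 11)
  expect_warning(marker_concordance(list(a = t1[0, ], b = t1[0, ])), "no shared")
})
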