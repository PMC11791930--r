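# Normalization and standardization chain.

test_that("internal-standard normalization divides rows by the IS column", {
  m <- prism_matrix(cbind(c(4, 4, 4), c(2, 4, 8)),
                    feature_mz = c(281.2485, 208.1140))
  out <- normalize_is(m, 208.1140)
  expect_equal(as.numeric(out$values[, 1]), c(2, 1, 0.5))
  expect_equal(max(abs(out$values[, 2] - 1)), 0)       # IS column becomes 1
  expect_equal(out$stage, "normalized")
  # a row whose entries equal its IS value maps to all 1
  m2 <- prism_matrix(cbind(c(7, 3), c(7, 3)), feature_mz = c(100, 208.1140))
  expect_true(all(normalize_is(m2, 208.1140)$values == 1))
})

test_that("rows without internal-standard signal are dropped, never zero-filled", {
  m <- prism_matrix(cbind(c(1, 2, 3), c(2, 0, 4)),
                    feature_mz = c(100, 208.1140),
                    object_ids = c("a", "b", "c"))
  out <- normalize_is(m, 208.1140)
  expect_equal(out$object_ids, c("a", "c"))
  expect_equal(nrow(out$values), 2L)
  all_bad <- prism_matrix(cbind(1, 0), feature_mz = c(100, 208.1140))
  expect_error(normalize_is(all_bad, 208.1140), "every row")
  expect_error(normalize_is(m, 999), "internal-standard")
})

test_that("TIC normalization divides by row sums and is scale invariant", {
  m <- prism_matrix(rbind(c(1, 1, 2), c(7, 7, 14)), feature_mz = c(1, 2, 3))
  out <- normalize_tic(m)
  expect_equal(as.numeric(out$values[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(out$values[1, ], out$values[2, ])       # row scaled by 7
  expect_equal(unname(rowSums(out$values)), c(1, 1))
})

test_that("z-standardization uses the population sd and flags constant columns", {
  m <- prism_matrix(cbind(c(1, 2, 3), c(5, 5, 5)), feature_mz = c(1, 2),
                    stage = "raw")
  z <- z_standardize(m)
  expect_equal(as.numeric(z$values[, 1]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)  # population sd
  expect_true(all(z$values[, 2] == 0))
  expect_equal(z$constant_features, c(FALSE, TRUE))
  set.seed(8)
  big <- z_standardize(prism_matrix(matrix(rexp(500), 100, 5),
                                    feature_mz = 1:5))
  expect_lt(max(abs(colMeans(big$values))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(big$values^2)) - 1)), 1e-9)
  expect_error(z_standardize(prism_matrix(matrix(1, 1, 2), feature_mz = 1:2)),
               "at least 2 rows")
})

test_that("IS normalization then standardization cancels per-row gain", {
  set.seed(9)
  raw <- matrix(rexp(200, 1 / 100), 40, 5)
  mzs <- c(100, 150, 208.1140, 250, 300)
  gains <- runif(40, 0.2, 5)   # simulated laser/matrix variation
  a <- z_standardize(normalize_is(prism_matrix(raw, mzs), 208.1140))
  b <- z_standardize(normalize_is(prism_matrix(raw * gains, mzs), 208.1140))
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("marker selection removes standardized intensities at or below the cutoff", {
  vals <- c(-1, 0, 2.9, 3.0, 3.1)
  m <- prism_matrix(cbind(vals), feature_mz = 281.2485,
                    object_ids = letters[1:5],
                    coords = data.frame(x = 0:4, y = 0))
  m$stage <- "standardized"
  sel <- select_marker_pixels(m, 281.2485, z_min = 3)
  expect_equal(sel$object_ids, "e")                    # 3.0 removed, 3.1 kept
  expect_equal(nrow(select_marker_pixels(m, 281.2485, z_min = -Inf)$values), 5L)
  expect_equal(nrow(select_marker_pixels(m, 281.2485, z_min = 99)$values), 0L)
})

test_that("union selection joins per-marker selections", {
  vals <- cbind(c(5, -1, -1), c(-1, 5, -1))
  m <- prism_matrix(vals, feature_mz = c(786.6007, 678.5068),
                    object_ids = c("dopc", "dmpc", "bg"),
                    coords = data.frame(x = 0:2, y = 0))
  m$stage <- "standardized"
  u <- select_union_pixels(m, c(786.6007, 678.5068), 3)
  expect_setequal(u$object_ids, c("dopc", "dmpc"))
  one <- select_marker_pixels(m, 786.6007, 3)
  expect_equal(select_union_pixels(m, 786.6007, 3)$object_ids, one$object_ids)
  # disjoint selections of sizes a and b give a union of size a + b
  expect_equal(nrow(u$values),
               nrow(one$values) + nrow(select_marker_pixels(m, 678.5068, 3)$values))
})
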