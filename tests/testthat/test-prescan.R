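# PreScan thresholding and mask operations.

test_that("ion images sum peaks within tolerance per pixel", {
  ds <- msi_dataset(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)),
                    mz = list(c(281.2480, 281.2490), 200.0, 281.2485),
                    intensity = list(c(3, 4), 9, 5),
                    pixel_size = 200, mode = "processed")
  img <- ion_image(ds, 281.2485, tol_ppm(10))
  expect_equal(img$grid, matrix(c(7, 5, 0, 0), 2, 2))  # two in-window peaks sum
  expect_warning(z <- ion_image(ds, 900, tol_ppm(10)), "outside")
  expect_true(all(z$grid == 0))
})

test_that("kappa follows mean + alpha * population sd over all cells", {
  img <- fake_image(matrix(c(0, 0, 0, 12), 2, 2))
  th <- compute_threshold(img, 1)
  expect_equal(th$mean, 3)
  expect_equal(th$sd, sqrt(27))           # population convention, zeros included
  expect_equal(th$kappa, 3 + sqrt(27))
  expect_equal(compute_threshold(img, 0)$kappa, 3)
  const <- compute_threshold(fake_image(matrix(4.2, 3, 3)), 7)
  expect_equal(const$kappa, 4.2)          # sd = 0
  expect_equal(sum(binarize(img, th)$grid), 1L)
})

test_that("binarization is strict at the threshold", {
  zero <- fake_image(matrix(0, 2, 2))
  expect_false(any(binarize(zero, list(kappa = 0))$grid))
  img <- fake_image(matrix(c(1, 2, 3, 4), 2, 2))
  expect_true(all(binarize(img, list(kappa = 0.5))$grid))
  expect_equal(sum(binarize(img, list(kappa = 3))$grid), 1L)  # ties excluded
})

test_that("kappa is monotone in alpha and mask count non-increasing", {
  set.seed(3)
  img <- fake_image(matrix(rexp(100, 1 / 50), 10, 10))
  alphas <- c(0, 0.5, 1, 2, 3)
  kappas <- vapply(alphas, function(a) compute_threshold(img, a)$kappa, numeric(1))
  counts <- vapply(kappas, function(k) sum(binarize(img, list(kappa = k))$grid),
                   numeric(1))
  expect_true(all(diff(kappas) > 0))
  expect_true(all(diff(counts) <= 0))
})

test_that("resizing expands true cells into blocks and conserves count", {
  one <- mask_of(matrix(TRUE, 1, 1))
  big <- resize_mask(one, 10)
  expect_equal(dim(big$grid), c(10L, 10L))
  expect_true(all(big$grid))
  expect_equal(big$pixel_size, 20)        # 200 um -> 20 um
  checker <- mask_of(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_identical(resize_mask(checker, 1)$grid, checker$grid)
  r2 <- resize_mask(checker, 2)
  expect_equal(sum(r2$grid), sum(checker$grid) * 4)
  expect_identical(r2$grid[1:2, 1:2], matrix(TRUE, 2, 2))
  expect_identical(r2$grid[1:2, 3:4], matrix(FALSE, 2, 2))
  set.seed(4)
  for (f in c(2L, 3L, 5L)) {
    m <- mask_of(matrix(runif(48) < 0.4, 6, 8))
    expect_equal(sum(resize_mask(m, f)$grid), sum(m$grid) * f^2)
  }
  expect_error(resize_mask(one, 2.5), "integer")
})

test_that("dilation grows by a square element and factor 1 is the identity", {
  m <- mask_of(matrix(FALSE, 5, 5)); m$grid[3, 3] <- TRUE
  expect_identical(dilate_mask(m, 1)$grid, m$grid)
  d2 <- dilate_mask(m, 2)
  expected <- matrix(FALSE, 5, 5); expected[2:4, 2:4] <- TRUE
  expect_identical(d2$grid, expected)
  # brute-force neighbourhood expansion oracle at factor 3
  set.seed(5)
  r <- mask_of(matrix(runif(100) < 0.2, 10, 10))
  d3 <- dilate_mask(r, 3)
  oracle <- matrix(FALSE, 10, 10)
  for (i in 1:10) for (j in 1:10)
    if (any(r$grid[max(1, i - 2):min(10, i + 2),
                   max(1, j - 2):min(10, j + 2)])) oracle[i, j] <- TRUE
  expect_identical(d3$grid, oracle)
  # never removes cells; saturates on the all-true mask
  expect_true(all(d3$grid[r$grid]))
  full <- mask_of(matrix(TRUE, 4, 4))
  expect_true(all(dilate_mask(full, 3)$grid))
})

test_that("mask evaluation computes FPR over negatives and FNR over positives", {
  g <- matrix(FALSE, 10, 10)
  truth <- mask_of(g); truth$grid[1:4, 1:5] <- TRUE          # 20 true
  pred <- mask_of(g)
  pred$grid[1, 1:5] <- TRUE                                  # 5 overlap
  pred$grid[7, 1:4] <- TRUE                                  # 4 spurious
  ev <- evaluate_mask(pred, truth)
  expect_equal(ev$false_negative_rate, 0.75)
  expect_equal(ev$false_positive_rate, 0.05)
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, 100)
  same <- evaluate_mask(truth, truth)
  expect_equal(same$false_positive_rate, 0)
  expect_equal(same$false_negative_rate, 0)
  none <- evaluate_mask(mask_of(g), truth)
  expect_equal(none$false_negative_rate, 1)
  expect_equal(none$false_positive_rate, 0)
  expect_warning(ev2 <- evaluate_mask(pred, mask_of(g)), "all-negative")
  expect_true(is.na(ev2$false_negative_rate))
})
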