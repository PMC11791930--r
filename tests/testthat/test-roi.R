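# ROI extraction: connected components, boundary polygons, region restriction.

test_that("a single true pixel yields its exact pixel square", {
  g <- matrix(FALSE, 3, 3); g[1, 1] <- TRUE
  rois <- extract_rois(mask_of(g, 20))
  expect_length(rois, 1L)
  p <- rois[[1]]$polygon
  expect_equal(abs(polygon_area(p)), 400)            # 20 x 20 um
  expect_equal(range(p[, 1]), c(0, 20))
  expect_equal(range(p[, 2]), c(0, 20))
  expect_gt(polygon_area(p), 0)                      # counter-clockwise
})

test_that("diagonally touching pixels form one region", {
  g <- matrix(FALSE, 4, 4); g[2, 2] <- TRUE; g[3, 3] <- TRUE
  rois <- extract_rois(mask_of(g, 20))
  expect_length(rois, 1L)
  expect_equal(abs(polygon_area(rois[[1]]$polygon)), 2 * 400)
})

test_that("holes are filled: a ring component yields one solid polygon", {
  g <- matrix(FALSE, 5, 5); g[2:4, 2:4] <- TRUE; g[3, 3] <- FALSE
  rois <- extract_rois(mask_of(g, 10))
  expect_length(rois, 1L)
  expect_equal(abs(polygon_area(rois[[1]]$polygon)), 9 * 100)  # hole included
})

test_that("component count matches flood fill on random masks", {
  set.seed(6)
  for (i in 1:60) {
    g <- matrix(runif(256) < runif(1, 0.1, 0.6), 16, 16)
    oracle <- oracle_flood_fill(g)
    got <- prismms:::label_components(g)
    expect_equal(max(got), max(oracle))
    # identical partitions up to label names
    if (max(oracle) > 0)
      expect_equal(got[g], oracle[g])  # both number in raster-scan order
    if (any(g)) {
      rois <- extract_rois(mask_of(g, 20))
      expect_length(rois, max(oracle))
      # total polygon area accounts for every pixel exactly once per component
      tot <- sum(vapply(rois, function(r) abs(polygon_area(r$polygon)), numeric(1)))
      filled <- sum(vapply(seq_len(max(oracle)), function(k)
        sum(prismms:::fill_holes(oracle == k)), numeric(1)))
      expect_equal(tot, filled * 400)
    }
  }
})

test_that("empty masks are refused with a distinct message", {
  expect_error(extract_rois(mask_of(matrix(FALSE, 3, 3))), "no cells found")
})

test_that("the emitted transform places polygons in stage coordinates", {
  g <- matrix(FALSE, 3, 3); g[2, 3] <- TRUE    # grid x = 2, y = 1
  tr <- cbind(diag(2) * 20, c(1000, 500))
  p <- extract_rois(mask_of(g, 20), transform = tr)[[1]]$polygon
  expect_equal(range(p[, 1]), 1000 + c(40, 60))
  expect_equal(range(p[, 2]), 500 + c(20, 40))
})

test_that("restriction keeps exactly the pixels inside region polygons", {
  ds <- msi_dataset(expand.grid(x = 0:9, y = 0:9),
                    mz = rep(list(100), 100),
                    intensity = rep(list(1), 100), pixel_size = 20)
  doc <- region_document("deep", 20, list(
    list(name = "A", polygon = rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40)))))
  got <- restrict_to_regions(ds, doc)
  # centres at 10, 30, 50 in x (3 columns) and 10, 30 in y (2 rows)
  expect_equal(nrow(got$coords), 6L)
  expect_true(all(got$coords$x < 3 & got$coords$y < 2))
  expect_true(all(got$coords$region_id == "A"))
})

test_that("every thresholded object lands inside an emitted region", {
  f <- generate_field(field_spec(n_objects = 40, field_um = c(2000, 2000),
                                 seed = 19))
  img <- ion_image(f$prescan, 786.6007, tol_ppm(10))
  img2 <- ion_image(f$prescan, 678.5068, tol_ppm(10))
  g <- binarize(img, compute_threshold(img, 1))$grid |
       binarize(img2, compute_threshold(img2, 1))$grid
  mask <- mask_of(g, f$prescan$pixel_size)
  rois <- extract_rois(resize_mask(mask, 10))
  doc <- region_document("deep", 20, rois)
  # objects whose PreScan pixel exceeded kappa: their centre pixel must be
  # inside some region polygon
  obj <- f$truth$objects
  pre_col <- floor(obj$x_um / 200); pre_row <- floor(obj$y_um / 200)
  hot <- g[cbind(pre_row + 1, pre_col + 1)]
  centers <- cbind(obj$x_um, obj$y_um)[hot, , drop = FALSE]
  inside <- rep(FALSE, nrow(centers))
  for (r in doc$regions)
    inside <- inside | prismms:::point_in_polygon(centers, r$polygon)
  expect_true(all(inside))
})
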