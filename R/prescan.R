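#' Ion image of a target m/z
#'
#' Sums, per pixel, all peak intensities within tolerance of the target mass
#' and lays them out on the full coordinate grid (absent pixels hold 0).
#' This is the image the PreScan threshold is computed on, e.g. for the
#' ubiquitous cell marker FA 18:1 `[M-H]-` at m/z 281.2485.
#'
#' @param dataset [msi_dataset()].
#' @param target_mz target mass (Da).
#' @param tol [tol_ppm()] or [tol_da()] window around `target_mz`.
#' @return object of class `ion_image`: list with `grid` (rows x cols
#'   intensity matrix, row = y, col = x), `target_mz`, `tol`, `pixel_size`.
#' @export
ion_image <- function(dataset, target_mz, tol = tol_ppm(10)) {
  stopifnot(inherits(dataset, "msi_dataset"))
  tol <- as_tol(tol)
  rng <- mz_range(dataset)
  w <- tol_width_da(tol, target_mz)
  if (target_mz + w < rng[1] || target_mz - w > rng[2])
    warning("target m/z ", target_mz,
            " lies outside the dataset m/z range; returning an all-zero image")
  nr <- max(dataset$coords$y) + 1L
  nc <- max(dataset$coords$x) + 1L
  grid <- matrix(0, nr, nc)
  for (i in seq_len(n_pixels(dataset))) {
    sel <- abs(dataset$mz[[i]] - target_mz) <= w
    if (any(sel))
      grid[dataset$coords$y[i] + 1L, dataset$coords$x[i] + 1L] <-
        sum(dataset$intensity[[i]][sel])
  }
  structure(list(grid = grid, target_mz = target_mz, tol = tol,
                 pixel_size = dataset$pixel_size),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image: m/z %.4f, %d x %d pixels of %g um, max %.3g>\n",
              x$target_mz, nrow(x$grid), ncol(x$grid), x$pixel_size,
              max(x$grid)))
  invisible(x)
}

#' PreScan intensity threshold
#'
#' The mask threshold kappa = mean + alpha * sd, computed over *all* grid
#' cells of the ion image, zeros included, with the population standard
#' deviation (divide by n). alpha defaults to 1 and can be raised to make
#' region selection stricter.
#'
#' @param image [ion_image()].
#' @param alpha dimensionless multiplier on the standard deviation.
#' @return object of class `threshold_spec`: list with `alpha`, `mean`,
#'   `sd`, `kappa`.
#' @export
compute_threshold <- function(image, alpha = 1) {
  stopifnot(inherits(image, "ion_image"), length(image$grid) >= 1L)
  v <- as.numeric(image$grid)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))  # population sd over the full image
  structure(list(alpha = alpha, mean = m, sd = s, kappa = m + alpha * s),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold: kappa = %.4g (mean %.4g + alpha %g * sd %.4g)>\n",
              x$kappa, x$mean, x$alpha, x$sd))
  invisible(x)
}

new_mask <- function(grid, pixel_size, provenance = NULL) {
  stopifnot(is.logical(grid), is.matrix(grid))
  structure(list(grid = grid, pixel_size = pixel_size,
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask: %d x %d pixels of %g um, %d true>\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, sum(x$grid)))
  invisible(x)
}

#' Binarize an ion image at a threshold
#'
#' A cell is true iff its intensity strictly exceeds kappa; the strict
#' inequality makes the all-zero image map to an all-false mask.
#'
#' @param image [ion_image()].
#' @param spec [compute_threshold()] result (or any list with `$kappa`).
#' @return `binary_mask` of the same shape.
#' @export
binarize <- function(image, spec) {
  stopifnot(inherits(image, "ion_image"))
  kappa <- spec$kappa
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  new_mask(image$grid > kappa, image$pixel_size,
           provenance = list(threshold = spec))
}

#' Resize a mask to a finer raster
#'
#' Each true cell becomes a `factor` x `factor` block of true cells, matching
#' the resolution change from the coarse PreScan raster to the fine DeepScan
#' raster (200 um -> 20 um is factor 10). The raster ratio must divide
#' evenly; non-integer factors are refused.
#'
#' @param mask `binary_mask`.
#' @param factor positive integer upscaling factor.
#' @return `binary_mask` with pixel size divided by `factor`.
#' @export
resize_mask <- function(mask, factor) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer (raster sizes must divide evenly)",
         call. = FALSE)
  factor <- as.integer(factor)
  g <- mask$grid[rep(seq_len(nrow(mask$grid)), each = factor),
                 rep(seq_len(ncol(mask$grid)), each = factor), drop = FALSE]
  new_mask(g, mask$pixel_size / factor, provenance = mask$provenance)
}

#' Dilate a mask
#'
#' Optional region-growing step before contour extraction. A dilation factor
#' of 1 means no change; factor `d` applies morphological dilation with a
#' square structuring element of side `2 * (d - 1) + 1`.
#'
#' @param mask `binary_mask`.
#' @param dilation_factor positive integer (1 = identity). Some protocols
#'   call this a "dilution factor"; it is the same parameter.
#' @return dilated `binary_mask`.
#' @export
dilate_mask <- function(mask, dilation_factor = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(dilation_factor) || length(dilation_factor) != 1L ||
      dilation_factor < 1 || dilation_factor != round(dilation_factor))
    stop("dilation_factor must be a positive integer", call. = FALSE)
  d <- as.integer(dilation_factor)
  prov <- mask$provenance
  prov$dilation_factor <- d
  if (d == 1L) { mask$provenance <- prov; return(mask) }
  side <- 2L * (d - 1L) + 1L
  g <- EBImage::dilate(mask$grid * 1, EBImage::makeBrush(side, shape = "box"))
  new_mask(g > 0.5, mask$pixel_size, provenance = prov)
}

#' Compare a predicted mask against ground truth
#'
#' False-positive rate over truth-negative cells, false-negative rate over
#' truth-positive cells, plus raw confusion counts.
#'
#' @param predicted,truth `binary_mask` objects of equal shape.
#' @return list with `false_positive_rate`, `false_negative_rate` and counts
#'   `tp`, `fp`, `tn`, `fn`. An all-negative truth leaves the FNR `NA` with a
#'   warning.
#' @export
evaluate_mask <- function(predicted, truth) {
  stopifnot(inherits(predicted, "binary_mask"), inherits(truth, "binary_mask"))
  if (!all(dim(predicted$grid) == dim(truth$grid)))
    stop("mask shapes differ", call. = FALSE)
  p <- predicted$grid; t_ <- truth$grid
  tp <- sum(p & t_); fp <- sum(p & !t_)
  fn <- sum(!p & t_); tn <- sum(!p & !t_)
  fnr <- if (tp + fn == 0L) {
    warning("truth mask is all-negative; false-negative rate undefined")
    NA_real_
  } else fn / (fn + tp)
  fpr <- if (fp + tn == 0L) NA_real_ else fp / (fp + tn)
  list(false_positive_rate = fpr, false_negative_rate = fnr,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
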