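#' MSI dataset
#'
#' In-memory carrier for mass spectrometry imaging data: one spectrum per
#' pixel on an integer grid. Grid coordinates are 0-based, `x` = column,
#' `y` = row, origin top-left (imzML files store 1-based positions; the
#' reader/writer converts). `mode` follows imzML: `"continuous"` datasets
#' share one m/z axis across pixels, `"processed"` datasets carry per-pixel
#' peak lists.
#'
#' @param coords data.frame with integer columns `x`, `y` (0-based grid
#'   indices), optionally `region_id` (character).
#' @param mz list of numeric vectors (one per pixel, each strictly
#'   increasing), or a single numeric vector shared by all pixels
#'   (continuous mode).
#' @param intensity list of numeric vectors, lengths matching `mz`.
#' @param pixel_size pixel edge length in micrometre.
#' @param mode `"continuous"` or `"processed"`.
#' @return object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensity, pixel_size,
                        mode = c("processed", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(coords), all(c("x", "y") %in% names(coords)))
  n <- nrow(coords)
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  if (anyNA(coords$x) || anyNA(coords$y) || any(coords$x < 0) || any(coords$y < 0))
    stop("pixel coordinates must be non-negative integers", call. = FALSE)
  if (anyDuplicated(coords[c("x", "y")]))
    stop("integrity error: duplicate pixel coordinates", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive number (micrometre)", call. = FALSE)
  if (is.numeric(mz) && !is.list(mz)) mz <- rep(list(as.numeric(mz)), n)
  stopifnot(is.list(mz), is.list(intensity),
            length(mz) == n, length(intensity) == n)
  for (i in seq_len(n)) {
    if (length(mz[[i]]) != length(intensity[[i]]))
      stop("pixel ", i, ": m/z and intensity lengths differ", call. = FALSE)
    if (is.unsorted(mz[[i]], strictly = TRUE))
      stop("pixel ", i, ": m/z values must be strictly increasing", call. = FALSE)
  }
  if (mode == "continuous" && n > 1L) {
    ref <- mz[[1L]]
    same <- vapply(mz, function(v) length(v) == length(ref) && all(v == ref), logical(1))
    if (!all(same))
      stop("continuous mode requires an identical m/z axis in every pixel",
           call. = FALSE)
  }
  structure(
    list(coords = coords, mz = mz, intensity = intensity,
         pixel_size = as.numeric(pixel_size), mode = mode),
    class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  npk <- vapply(x$mz, length, integer(1))
  cat(sprintf("<msi_dataset: %d pixels, %s mode, %g um pixels>\n",
              nrow(x$coords), x$mode, x$pixel_size))
  cat(sprintf("  grid extent: x 0..%d, y 0..%d; peaks/pixel: %d..%d\n",
              max(x$coords$x), max(x$coords$y), min(npk), max(npk)))
  rng <- range(unlist(x$mz, use.names = FALSE))
  cat(sprintf("  m/z range: %.4f..%.4f\n", rng[1], rng[2]))
  invisible(x)
}

n_pixels <- function(dataset) nrow(dataset$coords)

## Global m/z range of a dataset.
mz_range <- function(dataset) range(unlist(dataset$mz, use.names = FALSE))

#' Common m/z axis for a dataset
#'
#' Merges per-pixel peak masses into one axis by greedy single-linkage
#' grouping: sorted unique masses are split wherever the gap to the previous
#' mass exceeds the tolerance, and each group is represented by its mean.
#' For continuous-mode data this returns the shared axis unchanged.
#'
#' @param dataset [msi_dataset()].
#' @param tol [tol_ppm()] or [tol_da()]; peaks closer than this end up in the
#'   same bin.
#' @return numeric vector of bin-centre m/z values.
#' @export
common_axis <- function(dataset, tol = tol_ppm(10)) {
  if (dataset$mode == "continuous") return(dataset$mz[[1L]])
  masses <- sort(unique(unlist(dataset$mz, use.names = FALSE)))
  if (length(masses) <= 1L) return(masses)
  gap <- diff(masses)
  width <- tol_width_da(tol, masses[-length(masses)])
  grp <- cumsum(c(0, as.integer(gap > width)))
  as.numeric(tapply(masses, grp, mean))
}

#' Pixel-by-feature intensity matrix
#'
#' Projects every pixel spectrum onto the dataset's [common_axis()], summing
#' peaks that fall into the same bin, and returns the raw-stage feature
#' matrix the normalization chain starts from.
#'
#' @inheritParams common_axis
#' @return [prism_matrix()] at stage `"raw"` with pixel coordinates attached.
#' @export
pixel_matrix <- function(dataset, tol = tol_ppm(10)) {
  axis <- common_axis(dataset, tol)
  n <- n_pixels(dataset)
  vals <- matrix(0, nrow = n, ncol = length(axis))
  if (length(axis)) {
    # bin edges halfway between neighbouring axis masses
    edges <- c(-Inf, (axis[-length(axis)] + axis[-1L]) / 2, Inf)
    for (i in seq_len(n)) {
      if (!length(dataset$mz[[i]])) next
      bin <- findInterval(dataset$mz[[i]], edges)
      s <- vapply(split(dataset$intensity[[i]], bin), sum, numeric(1))
      vals[i, as.integer(names(s))] <- s
    }
  }
  ids <- sprintf("px_%d_%d", dataset$coords$x, dataset$coords$y)
  prism_matrix(vals, feature_mz = axis, object_ids = ids,
               coords = dataset$coords[, c("x", "y")], stage = "raw")
}
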