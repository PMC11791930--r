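#' Cluster marker-positive pixels into cell objects
#'
#' Groups the retained pixels into 8-connected components ("cells").
#' Components larger than `max_single_cell_pixels` are kept in the output
#' for audit but classified `aggregate_excluded` and omitted from downstream
#' statistics: in low-density cultures up to seven connected pixels define a
#' single cell, while larger components are cell aggregates (components
#' above `max_cluster_pixels` are always aggregates under the hard 20-pixel
#' exclusion).
#'
#' @param matrix [prism_matrix()] of marker-selected pixels with `coords`.
#' @param max_single_cell_pixels largest component still called a single
#'   cell (default 7).
#' @param max_cluster_pixels hard exclusion bound (default 20); kept as a
#'   separate documented parameter — any component above
#'   `max_single_cell_pixels` is excluded either way.
#' @return object of class `cell_set`: list with `cells` (a data.frame:
#'   `cell_id`, `n_pixels`, `classification`, `centroid_x`, `centroid_y` in
#'   micrometre), `pixel_sets` (list of per-cell coordinate data.frames) and
#'   the `pixel_size` used for centroids.
#' @export
cluster_cells <- function(matrix, max_single_cell_pixels = 7,
                          max_cluster_pixels = 20,
                          pixel_size = 1) {
  stopifnot(inherits(matrix, "prism_matrix"), !is.null(matrix$coords))
  coords <- matrix$coords
  comp <- label_pixel_set(coords)
  k <- if (length(comp)) max(comp) else 0L
  cells <- data.frame(cell_id = sprintf("cell_%03d", seq_len(k)),
                      n_pixels = integer(k),
                      classification = character(k),
                      centroid_x = numeric(k), centroid_y = numeric(k),
                      stringsAsFactors = FALSE)
  pixel_sets <- vector("list", k)
  for (i in seq_len(k)) {
    rows <- which(comp == i)
    pixel_sets[[i]] <- data.frame(x = coords$x[rows], y = coords$y[rows],
                                  row = rows)
    n <- length(rows)
    cells$n_pixels[i] <- n
    cells$classification[i] <-
      if (n <= max_single_cell_pixels) "single_cell" else "aggregate_excluded"
    cells$centroid_x[i] <- (mean(coords$x[rows]) + 0.5) * pixel_size
    cells$centroid_y[i] <- (mean(coords$y[rows]) + 0.5) * pixel_size
  }
  structure(list(cells = cells, pixel_sets = pixel_sets,
                 pixel_size = pixel_size,
                 max_single_cell_pixels = max_single_cell_pixels,
                 max_cluster_pixels = max_cluster_pixels),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  tab <- table(x$cells$classification)
  cat(sprintf("<cell_set: %d object(s); %s>\n", nrow(x$cells),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Mean spectrum per single cell
#'
#' Arithmetic per-feature mean over each retained cell's member pixels,
#' returning one row per `single_cell` object (aggregates stay excluded).
#' Row order follows the cell order.
#'
#' @param cells [cluster_cells()] result.
#' @param matrix [prism_matrix()] holding the member pixel rows (any stage);
#'   typically the same matrix the cells were clustered from, or the
#'   matching raw/normalized matrix for statistics on unscaled values.
#' @param include_aggregates keep aggregate components too (default FALSE).
#' @return [prism_matrix()] with one row per cell, same stage as the input.
#' @export
cell_mean_spectra <- function(cells, matrix, include_aggregates = FALSE) {
  stopifnot(inherits(cells, "cell_set"), inherits(matrix, "prism_matrix"),
            !is.null(matrix$coords))
  take <- if (include_aggregates) seq_len(nrow(cells$cells)) else
    which(cells$cells$classification == "single_cell")
  key <- paste(matrix$coords$x, matrix$coords$y)
  vals <- matrix(0, length(take), ncol(matrix$values))
  for (ii in seq_along(take)) {
    px <- cells$pixel_sets[[take[ii]]]
    rows <- match(paste(px$x, px$y), key)
    if (anyNA(rows))
      stop("cell ", cells$cells$cell_id[take[ii]],
           " has pixels missing from the matrix", call. = FALSE)
    vals[ii, ] <- colMeans(matrix$values[rows, , drop = FALSE])
  }
  prism_matrix(vals, matrix$feature_mz,
               object_ids = cells$cells$cell_id[take],
               coords = data.frame(
                 x = cells$cells$centroid_x[take] / cells$pixel_size - 0.5,
                 y = cells$cells$centroid_y[take] / cells$pixel_size - 0.5),
               stage = matrix$stage, normalization = matrix$normalization)
}
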