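#' Feature matrix
#'
#' Objects-by-features intensity matrix carried through the normalization
#' chain: `raw` (as extracted), `normalized` (per-row division by internal
#' standard or total ion current), `standardized` (per-column z-scale). The
#' three stages correspond to the matrices M, M' and M'' of the processing
#' chain.
#'
#' @param values numeric matrix, rows = objects (pixels or cells), columns =
#'   features.
#' @param feature_mz numeric vector of feature masses (Da), one per column.
#' @param object_ids row identifiers.
#' @param coords optional data.frame of pixel grid coordinates (`x`, `y`) per
#'   row.
#' @param stage `"raw"`, `"normalized"` or `"standardized"`.
#' @param normalization `NULL`, `"is"` or `"tic"`.
#' @param constant_features logical flag per column, set by [z_standardize()]
#'   for columns that were constant (mapped to all-zero).
#' @return object of class `prism_matrix`.
#' @export
prism_matrix <- function(values, feature_mz, object_ids = NULL, coords = NULL,
                         stage = c("raw", "normalized", "standardized"),
                         normalization = NULL, constant_features = NULL) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(feature_mz) == ncol(values))
  if (is.null(object_ids)) object_ids <- as.character(seq_len(nrow(values)))
  stopifnot(length(object_ids) == nrow(values))
  if (!is.null(coords)) stopifnot(nrow(coords) == nrow(values))
  colnames(values) <- sprintf("mz_%.4f", feature_mz)
  rownames(values) <- object_ids
  structure(list(values = values, feature_mz = as.numeric(feature_mz),
                 object_ids = as.character(object_ids), coords = coords,
                 stage = stage, normalization = normalization,
                 constant_features = constant_features),
            class = "prism_matrix")
}

#' @export
print.prism_matrix <- function(x, ...) {
  cat(sprintf("<prism_matrix: %d objects x %d features, stage %s%s>\n",
              nrow(x$values), ncol(x$values), x$stage,
              if (!is.null(x$normalization))
                paste0(" (", x$normalization, "-normalized)") else ""))
  invisible(x)
}

#' @export
dim.prism_matrix <- function(x) dim(x$values)

## Column index of the feature nearest mz within tol; error if none.
feature_column <- function(matrix, mz, tol = tol_ppm(10), what = "feature") {
  d <- abs(matrix$feature_mz - mz)
  j <- which.min(d)
  if (!length(j) || !mz_within(matrix$feature_mz[j], mz, tol))
    stop("no ", what, " column within tolerance of m/z ", mz, call. = FALSE)
  j
}

subset_rows <- function(matrix, keep) {
  prism_matrix(matrix$values[keep, , drop = FALSE], matrix$feature_mz,
               matrix$object_ids[keep],
               coords = if (!is.null(matrix$coords))
                 matrix$coords[keep, , drop = FALSE] else NULL,
               stage = matrix$stage, normalization = matrix$normalization,
               constant_features = matrix$constant_features)
}

#' Internal-standard normalization
#'
#' Divides every row by its intensity in the internal-standard column (e.g.
#' Trp-d5, m/z 208.1140 `[M-H]-`), so the IS column becomes identically 1.
#' Rows without IS signal (intensity <= 0) carry no valid normalization and
#' are dropped with a logged count — never silently zero-filled.
#'
#' @param matrix raw-stage [prism_matrix()].
#' @param is_mz internal-standard m/z (Da).
#' @param tol tolerance for locating the IS column.
#' @return normalized-stage [prism_matrix()].
#' @export
normalize_is <- function(matrix, is_mz = 208.1140, tol = tol_ppm(10)) {
  stopifnot(inherits(matrix, "prism_matrix"))
  if (matrix$stage != "raw")
    stop("normalize_is expects a raw-stage matrix", call. = FALSE)
  j <- feature_column(matrix, is_mz, tol, what = "internal-standard")
  is_vals <- matrix$values[, j]
  keep <- is.finite(is_vals) & is_vals > 0
  if (!all(keep))
    prism_log(sum(!keep), " row(s) dropped: no internal-standard signal")
  if (!any(keep))
    stop("every row lacks internal-standard signal", call. = FALSE)
  vals <- matrix$values[keep, , drop = FALSE] / is_vals[keep]
  out <- subset_rows(matrix, keep)
  out$values <- vals
  rownames(out$values) <- out$object_ids
  out$stage <- "normalized"
  out$normalization <- "is"
  out
}

#' Total-ion-current normalization
#'
#' Divides every row by its total intensity (row sum), the normalization
#' used for vesicle data where no internal standard is present. Zero-sum
#' rows are dropped with a logged count.
#'
#' @param matrix raw-stage [prism_matrix()].
#' @return normalized-stage [prism_matrix()].
#' @export
normalize_tic <- function(matrix) {
  stopifnot(inherits(matrix, "prism_matrix"))
  if (matrix$stage != "raw")
    stop("normalize_tic expects a raw-stage matrix", call. = FALSE)
  tic <- rowSums(matrix$values)
  keep <- is.finite(tic) & tic > 0
  if (!all(keep)) prism_log(sum(!keep), " row(s) dropped: zero total ion current")
  if (!any(keep)) stop("every row has zero total ion current", call. = FALSE)
  out <- subset_rows(matrix, keep)
  out$values <- matrix$values[keep, , drop = FALSE] / tic[keep]
  rownames(out$values) <- out$object_ids
  out$stage <- "normalized"
  out$normalization <- "tic"
  out
}

#' Z-scale standardization
#'
#' Centres and scales each feature column to mean 0 and standard deviation 1
#' (population convention, divide by n — the same convention used for the
#' PreScan threshold). Constant columns cannot be scaled; they map to
#' all-zero and are flagged in `constant_features`.
#'
#' @param matrix normalized-stage (or raw) [prism_matrix()] with >= 2 rows.
#' @return standardized-stage [prism_matrix()].
#' @export
z_standardize <- function(matrix) {
  stopifnot(inherits(matrix, "prism_matrix"))
  if (nrow(matrix$values) < 2L)
    stop("standardization needs at least 2 rows (sd undefined)", call. = FALSE)
  mu <- colMeans(matrix$values)
  centred <- sweep(matrix$values, 2, mu)
  sdev <- sqrt(colMeans(centred^2))  # population sd
  constant <- sdev == 0
  sdev[constant] <- 1  # constant columns map to all-zero
  out <- matrix
  out$values <- sweep(centred, 2, sdev, "/")
  out$stage <- "standardized"
  out$constant_features <- unname(constant)
  if (any(constant))
    prism_log(sum(constant), " constant feature column(s) mapped to zero")
  out
}

#' Select marker-positive pixels
#'
#' Retains rows whose standardized marker value strictly exceeds `z_min`
#' (default 3): pixels with standardized intensities <= 3 for the marker are
#' removed from the imaging dataset.
#'
#' @param matrix standardized-stage [prism_matrix()].
#' @param marker_mz marker feature m/z (Da).
#' @param z_min standardized-intensity cutoff (strict).
#' @param tol tolerance for locating the marker column.
#' @return [prism_matrix()] with the retained rows (possibly none, logged).
#' @export
select_marker_pixels <- function(matrix, marker_mz, z_min = 3,
                                 tol = tol_ppm(10)) {
  stopifnot(inherits(matrix, "prism_matrix"))
  if (matrix$stage != "standardized")
    stop("marker selection operates on the standardized matrix", call. = FALSE)
  j <- feature_column(matrix, marker_mz, tol, what = "marker")
  keep <- matrix$values[, j] > z_min
  if (!any(keep)) prism_log("marker selection at m/z ", marker_mz,
                            " retained no pixels")
  subset_rows(matrix, keep)
}

#' Select pixels positive for any of several markers
#'
#' Union of the per-marker selections: used for two-population vesicle
#' fields where the two marker lipids share no common peak, so the masks
#' from both peaks are added together.
#'
#' @inheritParams select_marker_pixels
#' @param marker_mzs numeric vector of marker masses (>= 1).
#' @return [prism_matrix()] with the union of retained rows (input order).
#' @export
select_union_pixels <- function(matrix, marker_mzs, z_min = 3,
                                tol = tol_ppm(10)) {
  stopifnot(inherits(matrix, "prism_matrix"), length(marker_mzs) >= 1L)
  keep <- rep(FALSE, nrow(matrix$values))
  for (mz in marker_mzs) {
    j <- feature_column(matrix, mz, tol, what = "marker")
    keep <- keep | matrix$values[, j] > z_min
  }
  subset_rows(matrix, keep)
}
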