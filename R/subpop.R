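#' Assign marker-based subpopulation labels
#'
#' Combines one M3C result per marker into a per-cell label over binary
#' marker axes (e.g. itaconate/taurine, or two vesicle lipids). For a marker
#' whose M3C selected k = 2, the cluster with the higher mean marker
#' intensity is the "+" side; a homogeneous marker labels every cell "-".
#' The final label is the cross-product, e.g. `"ita+taur-"`, and cells
#' negative on every axis are flagged `omit` so population statistics can
#' leave them out.
#'
#' @param cells cell-level [prism_matrix()] the M3C runs were computed on.
#' @param marker_results named list of [run_m3c()] results, one per marker;
#'   names are the marker short names used in the labels.
#' @param marker_mzs numeric vector (same order) of marker m/z values used
#'   to look up intensities; defaults to parsing `names(marker_results)` as
#'   numbers when possible.
#' @param tol tolerance for locating marker columns.
#' @return data.frame with one row per cell: `object_id`, one logical
#'   `<marker>_pos` column per marker, `label`, `omit`.
#' @export
assign_subpopulations <- function(cells, marker_results, marker_mzs = NULL,
                                  tol = tol_ppm(10)) {
  stopifnot(inherits(cells, "prism_matrix"), is.list(marker_results),
            length(marker_results) >= 1L)
  nms <- names(marker_results)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("marker_results must be a named list", call. = FALSE)
  if (is.null(marker_mzs)) {
    marker_mzs <- suppressWarnings(as.numeric(nms))
    if (anyNA(marker_mzs))
      stop("supply marker_mzs when marker names are not numeric", call. = FALSE)
  }
  n <- nrow(cells$values)
  out <- data.frame(object_id = cells$object_ids, stringsAsFactors = FALSE)
  for (i in seq_along(marker_results)) {
    res <- marker_results[[i]]
    stopifnot(inherits(res, "m3c"))
    pos <- rep(FALSE, n)
    if (!identical(res$selected_k, "homogeneous")) {
      if (res$selected_k != 2L)
        stop("marker '", nms[i], "' selected k = ", res$selected_k,
             "; binary +/- labelling is defined only for k = 2 (or homogeneous)",
             call. = FALSE)
      if (length(res$assignments) != n)
        stop("marker '", nms[i], "' was clustered on a different cell set",
             call. = FALSE)
      j <- feature_column(cells, marker_mzs[i], tol, what = "marker")
      means <- tapply(cells$values[, j], res$assignments, mean)
      pos_cluster <- as.integer(names(means)[which.max(means)])
      pos <- res$assignments == pos_cluster
    }
    out[[paste0(nms[i], "_pos")]] <- pos
  }
  pos_cols <- grep("_pos$", names(out))
  out$label <- apply(out[pos_cols], 1, function(v)
    paste0(sub("_pos$", "", names(out)[pos_cols]),
           ifelse(v, "+", "-"), collapse = ""))
  out$omit <- !Reduce(`|`, out[pos_cols])
  out
}

#' Per-condition subpopulation fractions
#'
#' Label fractions over the non-omitted cells of each condition, summing to
#' 1 per condition. Conditions whose cells are all omitted yield no row,
#' with a warning.
#'
#' @param labels [assign_subpopulations()] result.
#' @param group condition per cell (factor or character), or `NULL` for a
#'   single condition.
#' @return data.frame with columns `condition`, `label`, `n`, `fraction`.
#' @export
population_statistics <- function(labels, group = NULL) {
  stopifnot(is.data.frame(labels), "label" %in% names(labels))
  if (is.null(group)) group <- rep("all", nrow(labels))
  stopifnot(length(group) == nrow(labels))
  keep <- !labels$omit
  out <- NULL
  for (g in unique(as.character(group))) {
    sel <- keep & group == g
    if (!any(sel)) {
      warning("condition '", g, "' has no non-omitted cells; skipped")
      next
    }
    tab <- table(labels$label[sel])
    out <- rbind(out, data.frame(condition = g, label = names(tab),
                                 n = as.integer(tab),
                                 fraction = as.numeric(tab) / sum(tab),
                                 stringsAsFactors = FALSE))
  }
  out
}
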