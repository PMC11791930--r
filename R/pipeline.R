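## Pipeline orchestration: chain PreScan thresholding -> region emission ->
## DeepScan cell extraction -> per-feature M3C -> subpopulation labels, with
## a run manifest (config, seed, input digests, headline numbers) logged for
## every invocation.

PIPELINE_SECTIONS <- c("seed", "out_dir", "synth", "prescan", "cells", "m3c")

default_pipeline_config <- function() list(
  seed = 42,
  out_dir = NULL,
  synth = list(n = 300, mix = 0.5),
  prescan = list(imzml = NULL, mis = NULL,
                 target_mz = NULL,        # default: the population markers
                 tol_ppm = 10, alpha = 1, dilation = 1, deep_raster = 20),
  cells = list(imzml = NULL, normalization = "tic", is_mz = 208.1140,
               marker_mz = NULL, z_min = 3, max_cell_px = 7,
               max_cluster_px = 20),
  m3c = list(feature_mz = NULL, max_k = 4, iters = 100, ref_iters = 100,
             p_threshold = 0.01)
)

## Merge user config over defaults, rejecting unknown keys with their path.
merge_config <- function(user, defaults = default_pipeline_config(),
                         path = character(0)) {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(user))
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key: ",
         paste(c(path, bad[1]), collapse = "."), call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(user[[k]], defaults[[k]], c(path, k)) else user[[k]]
  }
  defaults
}

#' Run the two-pass single-cell pipeline
#'
#' Executes the full chain on either a synthetic ground-truth field (the
#' default, so the pipeline is runnable without instrument data) or on
#' supplied imzML/region files: PreScan ion images of the marker masses are
#' thresholded (kappa = mean + alpha sd), masks united, resized to the
#' DeepScan raster, optionally dilated, and turned into measurement regions;
#' the DeepScan is restricted to those regions, normalized (TIC or internal
#' standard), z-standardized and segmented into single-cell objects; each
#' marker feature is tested for subpopulation structure by M3C; and cells
#' are labelled by marker positivity. A run manifest is written when
#' `out_dir` is set.
#'
#' @param config named list or path to a YAML file; unknown keys are
#'   rejected with the offending key named. Sections and defaults: see the
#'   object returned by `prismms:::default_pipeline_config()`; any value
#'   supplied overrides the default.
#' @return list of class `prism_run`: stage outputs (`field`, `threshold`
#'   specs, `regions`, `cells`, `m3c`, `labels`, `population`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  t0 <- Sys.time()
  manifest <- list(timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   command = "run_pipeline",
                   package_version = as.character(utils::packageVersion("prismms")),
                   config = cfg, seed = cfg$seed, input_digests = list())

  # --- inputs: synthetic field or files ------------------------------------
  if (!is.null(cfg$prescan$imzml)) {
    pre <- read_imzml(cfg$prescan$imzml, cfg$prescan$tol_ppm)
    deep <- read_imzml(cfg$cells$imzml, cfg$prescan$tol_ppm)
    manifest$input_digests <- as.list(tools::md5sum(
      c(cfg$prescan$imzml, cfg$cells$imzml)))
    field <- NULL
    markers <- cfg$cells$marker_mz
    if (is.null(markers)) stop("cells.marker_mz required for file input", call. = FALSE)
  } else {
    spec <- field_spec(n_objects = cfg$synth$n, seed = cfg$seed)
    # population mix override (two populations)
    spec$populations[[1]]$fraction <- cfg$synth$mix
    spec$populations[[2]]$fraction <- 1 - cfg$synth$mix
    field <- generate_field(spec)
    pre <- field$prescan; deep <- field$deepscan
    markers <- cfg$cells$marker_mz
    if (is.null(markers))
      markers <- vapply(spec$populations, function(p)
        as.numeric(names(p$signature)[1]), numeric(1))
  }
  targets <- cfg$prescan$target_mz
  if (is.null(targets)) targets <- markers
  tol <- tol_ppm(cfg$prescan$tol_ppm)

  # --- PreScan: threshold each target mass, unite masks --------------------
  thresholds <- list()
  union_grid <- NULL
  for (mz in targets) {
    img <- ion_image(pre, mz, tol)
    th <- compute_threshold(img, cfg$prescan$alpha)
    thresholds[[sprintf("%.4f", mz)]] <- th
    m <- binarize(img, th)
    union_grid <- if (is.null(union_grid)) m$grid else union_grid | m$grid
  }
  mask <- new_mask(union_grid, pre$pixel_size)
  factor <- pre$pixel_size / cfg$prescan$deep_raster
  mask_fine <- dilate_mask(resize_mask(mask, factor), cfg$prescan$dilation)
  regions <- extract_rois(mask_fine)
  doc <- region_document("deepscan", cfg$prescan$deep_raster, regions)

  # --- cells ---------------------------------------------------------------
  deep_roi <- restrict_to_regions(deep, doc)
  raw <- pixel_matrix(deep_roi, tol)
  norm <- if (identical(cfg$cells$normalization, "is"))
    normalize_is(raw, cfg$cells$is_mz, tol) else normalize_tic(raw)
  std <- z_standardize(norm)
  selected <- select_union_pixels(std, markers, cfg$cells$z_min, tol)
  cells <- cluster_cells(selected, cfg$cells$max_cell_px,
                         cfg$cells$max_cluster_px,
                         pixel_size = deep$pixel_size)
  cell_norm <- cell_mean_spectra(cells, norm)
  cell_std <- z_standardize(cell_norm)

  # --- M3C per marker feature ----------------------------------------------
  feats <- cfg$m3c$feature_mz
  if (is.null(feats)) feats <- markers
  m3c_results <- list()
  for (mz in feats) {
    j <- feature_column(cell_std, mz, tol)
    m3c_results[[sprintf("%.4f", mz)]] <-
      run_m3c(cell_std$values[, j], max_k = cfg$m3c$max_k,
              iterations = cfg$m3c$iters, ref_iterations = cfg$m3c$ref_iters,
              p_threshold = cfg$m3c$p_threshold, seed = cfg$seed)
  }
  labels <- assign_subpopulations(cell_std, m3c_results,
                                  marker_mzs = feats, tol = tol)
  popstats <- population_statistics(labels)

  manifest$headline <- list(
    kappa = lapply(thresholds, function(t) t$kappa),
    prescan_true_pixels = sum(mask$grid),
    n_regions = length(regions),
    n_roi_pixels = n_pixels(deep_roi),
    n_selected_pixels = nrow(selected$values),
    n_objects = nrow(cells$cells),
    n_single_cells = sum(cells$cells$classification == "single_cell"),
    selected_k = lapply(m3c_results, function(r) r$selected_k))

  out <- structure(list(field = field, thresholds = thresholds, mask = mask,
                        regions = doc, cells = cells, cell_matrix = cell_std,
                        m3c = m3c_results, labels = labels,
                        population = popstats, manifest = manifest),
                   class = "prism_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mis(doc, file.path(cfg$out_dir, "deepscan.mis"))
    utils::write.csv(cbind(cells$cells), file.path(cfg$out_dir, "cells.csv"),
                     row.names = FALSE)
    write_manifest(manifest, file.path(cfg$out_dir, "manifest.json"))
  }
  out
}

#' @export
print.prism_run <- function(x, ...) {
  h <- x$manifest$headline
  cat(sprintf("<prism_run: %d region(s), %d single cell(s) of %d object(s)>\n",
              h$n_regions, h$n_single_cells, h$n_objects))
  for (nm in names(h$selected_k))
    cat(sprintf("  m/z %s: selected k = %s\n", nm, h$selected_k[[nm]]))
  invisible(x)
}

#' Write a run manifest
#'
#' Serializes the manifest (timestamp, command, configuration, seed, input
#' digests, headline numbers) as JSON; every pipeline/CLI invocation emits
#' exactly one.
#'
#' @param manifest manifest list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
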