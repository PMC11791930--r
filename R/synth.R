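#' Synthetic field specification
#'
#' Describes a ground-truth field of cell-sized objects (e.g. giant
#' unilamellar vesicles of two lipid compositions) on a slide area scanned
#' twice: a coarse PreScan raster and a fine DeepScan raster. Objects carry
#' population-specific feature signatures with log-normal intensity noise;
#' background matrix peaks and an internal-standard channel are present in
#' every pixel. The defaults emulate a 1:1 two-lipid vesicle mixture with
#' 5-50 um object diameters, a 200-um PreScan and a 20-um DeepScan.
#'
#' @param field_um field width and height in micrometre.
#' @param n_objects number of objects to place (non-overlapping).
#' @param diameter_um range of object diameters (uniform draw), micrometre.
#' @param populations list of `list(name =, fraction =, signature =)`;
#'   `signature` is a named numeric vector mapping feature m/z (as names) to
#'   mean log-intensity. Fractions must sum to 1.
#' @param noise_sigma log-normal sigma of per-pixel feature intensities.
#' @param background data.frame with columns `mz`, `meanlog`: matrix peaks
#'   present in every pixel.
#' @param is_mz,is_meanlog internal-standard channel (present in every
#'   pixel); `is_mz = NULL` omits it.
#' @param prescan_pixel,deepscan_pixel raster step sizes in micrometre;
#'   `deepscan_pixel` must divide `prescan_pixel` and both must divide the
#'   field edges.
#' @param acq_noise_sigma multiplicative log-normal noise applied to PreScan
#'   pixel sums (0 = PreScan exactly sums its DeepScan children).
#' @param seed RNG seed for [generate_field()].
#' @return object of class `field_spec`.
#' @export
field_spec <- function(field_um = c(4000, 4000), n_objects = 300,
                       diameter_um = c(5, 50),
                       populations = list(
                         list(name = "DOPC", fraction = 0.5,
                              signature = c("786.6007" = log(5000),
                                            "522.3559" = log(800))),
                         list(name = "DMPC", fraction = 0.5,
                              signature = c("678.5068" = log(5000),
                                            "700.4888" = log(800)))),
                       noise_sigma = 0.3,
                       background = data.frame(mz = 157.0771,
                                               meanlog = log(300)),
                       is_mz = 208.1140, is_meanlog = log(1000),
                       prescan_pixel = 200, deepscan_pixel = 20,
                       acq_noise_sigma = 0.1, seed = 42) {
  stopifnot(length(field_um) == 2L, all(field_um > 0),
            n_objects >= 0, length(diameter_um) == 2L, all(diameter_um > 0),
            prescan_pixel > 0, deepscan_pixel > 0)
  if (prescan_pixel %% deepscan_pixel != 0)
    stop("deepscan_pixel must divide prescan_pixel", call. = FALSE)
  if (any(field_um %% prescan_pixel != 0))
    stop("prescan_pixel must divide both field edges", call. = FALSE)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("population fractions must sum to 1", call. = FALSE)
  structure(list(field_um = field_um, n_objects = n_objects,
                 diameter_um = sort(diameter_um), populations = populations,
                 noise_sigma = noise_sigma, background = background,
                 is_mz = is_mz, is_meanlog = is_meanlog,
                 prescan_pixel = prescan_pixel, deepscan_pixel = deepscan_pixel,
                 acq_noise_sigma = acq_noise_sigma, seed = seed),
            class = "field_spec")
}

#' Generate a synthetic two-pass imaging field
#'
#' Places non-overlapping discs (rejection sampling with bounded retries),
#' assigns each to a population by the spec's fractions, rasterizes at the
#' DeepScan step (a pixel belongs to an object iff the pixel centre lies
#' inside the disc; pixels reachable from two near-touching objects go to
#' the nearer centre) and draws per-pixel feature intensities log-normally
#' around the population signature. Background peaks and the
#' internal-standard channel appear in every pixel. The PreScan dataset
#' holds, per coarse pixel, the sum of its DeepScan children's intensities
#' times multiplicative acquisition noise. Fully deterministic given the
#' spec's seed.
#'
#' @param spec [field_spec()].
#' @return list of class `synthetic_field`: `prescan` and `deepscan`
#'   ([msi_dataset()], continuous mode), `truth` (list with `objects`
#'   data.frame and `pixel_map` of covered DeepScan pixels), and `spec`.
#' @export
generate_field <- function(spec = field_spec()) {
  stopifnot(inherits(spec, "field_spec"))
  with_private_seed(spec$seed, {
    W <- spec$field_um[1]; H <- spec$field_um[2]
    # object placement
    n <- spec$n_objects
    pop_names <- vapply(spec$populations, `[[`, character(1), "name")
    fr <- vapply(spec$populations, `[[`, numeric(1), "fraction")
    cx <- cy <- dia <- numeric(0)
    pop <- character(0)
    attempts <- 0L
    max_attempts <- max(1000L, 200L * n)
    while (length(cx) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      d <- runif(1, spec$diameter_um[1], spec$diameter_um[2])
      r <- d / 2
      x <- runif(1, r, W - r); y <- runif(1, r, H - r)
      if (length(cx) == 0 ||
          all(sqrt((cx - x)^2 + (cy - y)^2) > (dia / 2 + r))) {
        cx <- c(cx, x); cy <- c(cy, y); dia <- c(dia, d)
        pop <- c(pop, sample(pop_names, 1, prob = fr))
      }
    }
    if (length(cx) < n)
      stop("object density too high for non-overlapping placement: placed ",
           length(cx), " of ", n, " objects", call. = FALSE)
    objects <- data.frame(object_id = seq_len(n), x_um = cx, y_um = cy,
                          diameter_um = dia, population = pop,
                          stringsAsFactors = FALSE)

    # DeepScan rasterization: pixel centre inside disc; contested pixels go
    # to the nearer centre
    dp <- spec$deepscan_pixel
    ncx <- as.integer(W / dp); ncy <- as.integer(H / dp)
    owner <- matrix(0L, ncy, ncx)
    owner_dist <- matrix(Inf, ncy, ncx)
    for (i in seq_len(n)) {
      r <- dia[i] / 2
      xs <- floor((cx[i] - r) / dp):floor((cx[i] + r) / dp)
      ys <- floor((cy[i] - r) / dp):floor((cy[i] + r) / dp)
      xs <- xs[xs >= 0 & xs < ncx]; ys <- ys[ys >= 0 & ys < ncy]
      for (gx in xs) for (gy in ys) {
        px <- (gx + 0.5) * dp; py <- (gy + 0.5) * dp
        dd <- sqrt((px - cx[i])^2 + (py - cy[i])^2)
        if (dd <= r && dd < owner_dist[gy + 1L, gx + 1L]) {
          owner[gy + 1L, gx + 1L] <- i
          owner_dist[gy + 1L, gx + 1L] <- dd
        }
      }
    }

    # feature axis: union of signatures, background, internal standard
    sig_mz <- sort(unique(as.numeric(unlist(
      lapply(spec$populations, function(p) names(p$signature))))))
    axis <- sort(unique(c(sig_mz, spec$background$mz,
                          if (!is.null(spec$is_mz)) spec$is_mz)))
    npx <- ncx * ncy
    vals <- matrix(0, npx, length(axis))
    # pixel order: row-major over the grid (y outer, x inner)
    gx <- rep(0:(ncx - 1L), times = ncy)
    gy <- rep(0:(ncy - 1L), each = ncx)
    draw <- function(npix, meanlog)
      exp(rnorm(npix, meanlog, spec$noise_sigma))
    for (b in seq_len(nrow(spec$background)))
      vals[, match(spec$background$mz[b], axis)] <-
        draw(npx, spec$background$meanlog[b])
    if (!is.null(spec$is_mz))
      vals[, match(spec$is_mz, axis)] <- draw(npx, spec$is_meanlog)
    own_vec <- as.integer(t(owner))  # matches row-major pixel order
    px_pop <- rep(NA_character_, npx)
    px_pop[own_vec > 0] <- pop[own_vec[own_vec > 0]]
    for (p in spec$populations) {
      rows <- which(!is.na(px_pop) & px_pop == p$name)
      if (!length(rows)) next
      for (f in seq_along(p$signature)) {
        j <- match(as.numeric(names(p$signature)[f]), axis)
        vals[rows, j] <- vals[rows, j] + draw(length(rows), p$signature[[f]])
      }
    }
    deep <- msi_dataset(data.frame(x = gx, y = gy),
                        mz = axis,
                        intensity = lapply(seq_len(npx), function(i) vals[i, ]),
                        pixel_size = dp, mode = "continuous")

    # PreScan: per coarse pixel, sum of its children, times acquisition noise
    f <- as.integer(spec$prescan_pixel / dp)
    pcx <- ncx %/% f; pcy <- ncy %/% f
    parent <- (gy %/% f) * pcx + (gx %/% f)  # 0-based parent index, row-major
    sums <- rowsum(vals, parent)
    ord <- order(as.integer(rownames(sums)))
    sums <- sums[ord, , drop = FALSE]
    if (spec$acq_noise_sigma > 0)
      sums <- sums * exp(matrix(rnorm(length(sums), 0, spec$acq_noise_sigma),
                                nrow(sums)))
    pg <- as.integer(rownames(sums))
    pre <- msi_dataset(data.frame(x = pg %% pcx, y = pg %/% pcx),
                       mz = axis,
                       intensity = lapply(seq_len(nrow(sums)), function(i) sums[i, ]),
                       pixel_size = spec$prescan_pixel, mode = "continuous")

    covered <- which(own_vec > 0)
    truth <- list(objects = objects,
                  pixel_map = data.frame(x = gx[covered], y = gy[covered],
                                         object_id = own_vec[covered]))
    structure(list(prescan = pre, deepscan = deep, truth = truth, spec = spec),
              class = "synthetic_field")
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field: %d objects (%s) on %g x %g um>\n",
              nrow(x$truth$objects),
              paste(names(table(x$truth$objects$population)),
                    table(x$truth$objects$population),
                    sep = " = ", collapse = ", "),
              x$spec$field_um[1], x$spec$field_um[2]))
  invisible(x)
}

#' Ground-truth occupancy mask
#'
#' Binary mask marking grid cells covered by any planted object, on the
#' DeepScan or PreScan raster (a PreScan cell is true iff any of its
#' DeepScan children is covered) — the reference for [evaluate_mask()].
#'
#' @param field [generate_field()] result.
#' @param raster `"deepscan"` or `"prescan"`.
#' @return `binary_mask`.
#' @export
truth_mask <- function(field, raster = c("deepscan", "prescan")) {
  raster <- match.arg(raster)
  stopifnot(inherits(field, "synthetic_field"))
  spec <- field$spec
  dp <- spec$deepscan_pixel
  ncx <- as.integer(spec$field_um[1] / dp)
  ncy <- as.integer(spec$field_um[2] / dp)
  g <- matrix(FALSE, ncy, ncx)
  pm <- field$truth$pixel_map
  g[cbind(pm$y + 1L, pm$x + 1L)] <- TRUE
  if (raster == "deepscan") return(new_mask(g, dp))
  f <- as.integer(spec$prescan_pixel / dp)
  pcy <- ncy %/% f; pcx <- ncx %/% f
  pg <- matrix(FALSE, pcy, pcx)
  for (r in seq_len(pcy)) for (c in seq_len(pcx)) {
    pg[r, c] <- any(g[((r - 1L) * f + 1L):(r * f), ((c - 1L) * f + 1L):(c * f)])
  }
  new_mask(pg, spec$prescan_pixel)
}

#' Generate a cell-level activation experiment
#'
#' Draws a standardized-scale cell-by-feature matrix emulating a
#' stimulus-response experiment: a fraction of cells is "activated", with
#' up-markers shifted by `+effect_size` and down-markers by `-effect_size`
#' standard deviations; all other features are null (standard normal).
#' Defaults use the itaconate-up / taurine-down marker pair.
#'
#' @param n_cells number of cells.
#' @param activated_fraction fraction of activated cells in `[0, 1]`
#'   (deterministic count, `round(n_cells * activated_fraction)`).
#' @param marker_up,marker_down m/z of up- and down-shifted markers.
#' @param effect_size shift in standardized units.
#' @param n_null_features number of additional null features.
#' @param seed RNG seed.
#' @return list: `cells` ([prism_matrix()], standardized scale), `activated`
#'   (logical ground truth per cell).
#' @export
generate_activation_experiment <- function(n_cells = 1000,
                                           activated_fraction = 0.5,
                                           marker_up = 129.0193,
                                           marker_down = 124.0074,
                                           effect_size = 2,
                                           n_null_features = 20, seed = 42) {
  stopifnot(activated_fraction >= 0, activated_fraction <= 1, n_cells >= 2)
  with_private_seed(seed, {
    n_act <- round(n_cells * activated_fraction)
    activated <- c(rep(TRUE, n_act), rep(FALSE, n_cells - n_act))
    mzs <- c(marker_up, marker_down,
             seq(300, 800, length.out = n_null_features))
    vals <- matrix(rnorm(n_cells * length(mzs)), n_cells)
    vals[activated, 1] <- vals[activated, 1] + effect_size
    vals[activated, 2] <- vals[activated, 2] - effect_size
    cells <- prism_matrix(vals, feature_mz = mzs,
                          object_ids = sprintf("cell_%04d", seq_len(n_cells)),
                          stage = "standardized")
    list(cells = cells, activated = activated)
  })
}
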