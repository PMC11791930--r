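#' Cohen's D effect size
#'
#' Standardized mean difference `(mu1 - mu2) / sigma`. On z-standardized
#' data the pooled standard deviation is 1 by construction, so the default
#' path is the plain mean difference; with `assume_unit_sd = FALSE` the
#' pooled-sd denominator is used instead. Sign convention: group1 minus
#' group2 (treatment minus vehicle makes activation markers positive).
#'
#' @param group1,group2 numeric vectors with at least 2 values each.
#' @param assume_unit_sd take the denominator as 1 (standardized data).
#' @return effect size (dimensionless).
#' @export
cohens_d <- function(group1, group2, assume_unit_sd = TRUE) {
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  delta <- mean(group1) - mean(group2)
  if (assume_unit_sd) return(delta)
  n1 <- length(group1); n2 <- length(group2)
  pooled <- sqrt(((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) /
                 (n1 + n2 - 2))
  if (pooled == 0) stop("pooled standard deviation is zero", call. = FALSE)
  delta / pooled
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1, input order
#' preserved) via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

volcano_class <- function(d, p_adj, d_threshold, p_threshold) {
  ifelse(p_adj < p_threshold & d > d_threshold, "up",
         ifelse(p_adj < p_threshold & d < -d_threshold, "down", "ns"))
}

#' Effect-size volcano table
#'
#' Per-feature Cohen's D and Benjamini-Hochberg-adjusted p-values comparing
#' two groups of objects, classified `up` / `down` / `ns` at the given
#' thresholds (a feature is relevant if |D| exceeds `d_threshold` *and* the
#' adjusted p is below `p_threshold`; the workflow defaults are 0.2 and
#' 0.05). Features constant in both groups are untestable: they are
#' classified `ns` with p set to 1 and flagged.
#'
#' @param group1,group2 [prism_matrix()] objects (or plain matrices) with
#'   identical feature sets; rows are independent objects (cells). Sign
#'   convention: D = mean(group1) - mean(group2).
#' @param d_threshold Cohen's D threshold (default 0.2).
#' @param p_threshold adjusted-p threshold (default 0.05).
#' @param assume_unit_sd see [cohens_d()]; default TRUE for standardized
#'   matrices.
#' @param test two-sample test generating the raw p-values: Welch's t-test
#'   (default) or Mann-Whitney.
#' @return data.frame of class `prism_volcano`: `mz`, `cohens_d`, `p_raw`,
#'   `p_adj`, `class`, `untestable`.
#' @export
volcano <- function(group1, group2, d_threshold = 0.2, p_threshold = 0.05,
                    assume_unit_sd = TRUE, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  mz1 <- if (inherits(group1, "prism_matrix")) group1$feature_mz else NULL
  v1 <- if (inherits(group1, "prism_matrix")) group1$values else as.matrix(group1)
  v2 <- if (inherits(group2, "prism_matrix")) group2$values else as.matrix(group2)
  if (ncol(v1) != ncol(v2)) stop("feature sets differ", call. = FALSE)
  if (nrow(v1) < 2L || nrow(v2) < 2L)
    stop("each group needs at least 2 objects", call. = FALSE)
  mz <- if (!is.null(mz1)) mz1 else seq_len(ncol(v1))
  p_raw <- d <- numeric(ncol(v1))
  untestable <- logical(ncol(v1))
  for (j in seq_len(ncol(v1))) {
    a <- v1[, j]; b <- v2[, j]
    if (sd(a) == 0 && sd(b) == 0) {
      untestable[j] <- TRUE
      p_raw[j] <- 1
      d[j] <- if (assume_unit_sd) mean(a) - mean(b) else 0
      next
    }
    d[j] <- cohens_d(a, b, assume_unit_sd = assume_unit_sd)
    p_raw[j] <- if (test == "welch") t.test(a, b)$p.value
                else wilcox.test(a, b, exact = FALSE)$p.value
  }
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(mz = mz, cohens_d = d, p_raw = p_raw, p_adj = p_adj,
                    class = volcano_class(d, p_adj, d_threshold, p_threshold),
                    untestable = untestable, stringsAsFactors = FALSE)
  out$class[untestable] <- "ns"
  attr(out, "d_threshold") <- d_threshold
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("prism_volcano", "data.frame")
  out
}

#' @export
print.prism_volcano <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("up", "down", "ns")))
  cat(sprintf("<volcano: %d features; up %d, down %d, ns %d (|D| > %g, p_adj < %g)>\n",
              nrow(x), tab["up"], tab["down"], tab["ns"],
              attr(x, "d_threshold"), attr(x, "p_threshold")))
  NextMethod()
}

#' Volcano plot
#'
#' Cohen's D against -log10 adjusted p, with the classification thresholds
#' drawn as dashed lines.
#'
#' @param x `prism_volcano` table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prism_volcano <- function(x, ...) {
  col <- c(up = "firebrick", down = "royalblue", ns = "grey60")[x$class]
  graphics::plot(x$cohens_d, -log10(pmax(x$p_adj, 1e-300)), col = col,
                 pch = 19, xlab = "Cohen's D", ylab = "-log10 adjusted p", ...)
  graphics::abline(v = c(-1, 1) * attr(x, "d_threshold"), lty = 2)
  graphics::abline(h = -log10(attr(x, "p_threshold")), lty = 2)
  invisible(x)
}

#' Pixel-subsampled volcano statistics for tissue data
#'
#' Adjacent tissue pixels are not independent, so tissue comparisons draw
#' `n_per_condition` random pixels per condition, compute the volcano table,
#' repeat `repeats` times and average: per feature the mean Cohen's D and
#' the mean raw and adjusted p-values across repeats (classification applies
#' the thresholds to the averaged adjusted p and averaged D). Conditions
#' with fewer pixels than requested use all pixels, with a warning.
#'
#' @param pixels_by_condition named list of exactly two [prism_matrix()]
#'   objects (or matrices), pixels as rows. D follows group1 - group2 in
#'   list order.
#' @param n_per_condition pixels sampled per condition (default 1000).
#' @param repeats number of independent subsamples (default 10).
#' @param seed RNG seed; caller's RNG state is untouched.
#' @inheritParams volcano
#' @return `prism_volcano` table of averaged statistics (`p_raw`, `p_adj`
#'   are means across repeats).
#' @export
subsample_pixels <- function(pixels_by_condition, n_per_condition = 1000,
                             repeats = 10, seed = 42, d_threshold = 0.2,
                             p_threshold = 0.05, assume_unit_sd = TRUE,
                             test = "welch") {
  stopifnot(is.list(pixels_by_condition), length(pixels_by_condition) == 2L)
  mats <- lapply(pixels_by_condition, function(m)
    if (inherits(m, "prism_matrix")) m$values else as.matrix(m))
  mz <- if (inherits(pixels_by_condition[[1]], "prism_matrix"))
    pixels_by_condition[[1]]$feature_mz else seq_len(ncol(mats[[1]]))
  for (i in 1:2)
    if (nrow(mats[[i]]) < n_per_condition)
      warning("condition ", i, " has only ", nrow(mats[[i]]),
              " pixels (< ", n_per_condition, "); sampling all of them")
  with_private_seed(seed, {
    acc_d <- acc_p <- acc_padj <- 0
    for (r in seq_len(repeats)) {
      sub <- lapply(mats, function(m)
        m[sample.int(nrow(m), min(n_per_condition, nrow(m))), , drop = FALSE])
      vt <- volcano(sub[[1]], sub[[2]], d_threshold, p_threshold,
                    assume_unit_sd = assume_unit_sd, test = test)
      acc_d <- acc_d + vt$cohens_d
      acc_p <- acc_p + vt$p_raw
      acc_padj <- acc_padj + vt$p_adj
    }
    d <- acc_d / repeats
    p_raw <- acc_p / repeats
    p_adj <- acc_padj / repeats
    out <- data.frame(mz = mz, cohens_d = d, p_raw = p_raw, p_adj = p_adj,
                      class = volcano_class(d, p_adj, d_threshold, p_threshold),
                      untestable = FALSE, stringsAsFactors = FALSE)
    attr(out, "d_threshold") <- d_threshold
    attr(out, "p_threshold") <- p_threshold
    attr(out, "repeats") <- repeats
    class(out) <- c("prism_volcano", "data.frame")
    out
  })
}

#' Trend concordance across volcano tables
#'
#' For features shared by all tables, reports each table's class and whether
#' the non-ns classes agree (same direction, no table calling it ns) — the
#' check used to ask how many marker candidates show the same trend across
#' model systems.
#'
#' @param tables named list (>= 2) of `prism_volcano` tables.
#' @return data.frame: `mz`, one class column per table, `concordant`.
#' @export
marker_concordance <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be named", call. = FALSE)
  shared <- Reduce(intersect, lapply(tables, function(t) t$mz))
  if (!length(shared)) {
    warning("no shared features between tables")
    return(data.frame(mz = numeric(0)))
  }
  out <- data.frame(mz = shared)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    out[[nm]] <- t$class[match(shared, t$mz)]
  }
  cls <- as.matrix(out[names(tables)])
  out$concordant <- apply(cls, 1, function(v)
    all(v != "ns") && length(unique(v)) == 1L)
  out
}
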