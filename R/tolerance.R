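#' Mass tolerances
#'
#' Two tolerance semantics coexist in the workflow and are never converted
#' silently into one another: read-time peak alignment uses parts-per-million
#' (default 10 ppm), while annotation-based peak reduction uses an absolute
#' window in Dalton (default +/- 0.005 Da). `tol_ppm()` and `tol_da()` build
#' explicit tolerance objects; every function taking a `tol` argument accepts
#' either kind.
#'
#' @param value positive tolerance value (ppm or Da).
#' @return an object of class `prism_tol` with fields `value` and `kind`.
#' @examples
#' tol_ppm(10)
#' tol_da(0.005)
#' @export
tol_ppm <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = as.numeric(value), kind = "ppm"), class = "prism_tol")
}

#' @rdname tol_ppm
#' @export
tol_da <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = as.numeric(value), kind = "da"), class = "prism_tol")
}

#' @export
print.prism_tol <- function(x, ...) {
  cat(sprintf("<tolerance: %g %s>\n", x$value,
              if (x$kind == "ppm") "ppm" else "Da"))
  invisible(x)
}

as_tol <- function(tol) {
  if (inherits(tol, "prism_tol")) return(tol)
  stop("supply a tolerance built with tol_ppm() or tol_da()", call. = FALSE)
}

## Half-width of the tolerance window around a reference m/z, in Da.
tol_width_da <- function(tol, mz) {
  tol <- as_tol(tol)
  if (tol$kind == "ppm") mz * tol$value * 1e-6 else tol$value
}

## TRUE where observed lies within tol of reference (vectorised over observed).
mz_within <- function(observed, reference, tol) {
  abs(observed - reference) <= tol_width_da(tol, reference)
}
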