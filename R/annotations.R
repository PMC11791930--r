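#' Read an annotation table
#'
#' Loads a delimited metabolite-annotation export (header
#' `formula,adduct,mz,fdr`), the format produced by FDR-controlled annotation
#' engines. FDR values are fractions in `[0, 1]`.
#'
#' @param path delimited text file with a header row.
#' @param sep field separator (default comma).
#' @return validated data.frame with columns `formula`, `adduct`, `mz`, `fdr`.
#' @export
read_annotations <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  need <- c("formula", "adduct", "mz", "fdr")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$mz <- as.numeric(df$mz)
  df$fdr <- as.numeric(df$fdr)
  if (any(!is.finite(df$mz)) || any(df$mz <= 0))
    stop("annotation m/z values must be positive numbers", call. = FALSE)
  if (any(!is.finite(df$fdr)) || any(df$fdr < 0 | df$fdr > 1))
    stop("annotation FDR values must lie in [0, 1]", call. = FALSE)
  df[need]
}

#' Reduce a dataset to annotated peaks
#'
#' Keeps only peaks lying within an absolute mass window of some annotation
#' that passes the FDR filter; every pixel is retained (possibly with an
#' empty spectrum). Defaults follow the workflow: +/- 0.005 Da around
#' annotations with FDR at most 10 %.
#'
#' @param dataset [msi_dataset()].
#' @param annotations annotation table (see [read_annotations()]).
#' @param tol_da absolute half-window in Da.
#' @param max_fdr maximum annotation FDR retained (fraction).
#' @return filtered [msi_dataset()] with the same pixel set.
#' @export
reduce_to_annotated <- function(dataset, annotations, tol_da = 0.005,
                                max_fdr = 0.10) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!is.numeric(tol_da) || tol_da <= 0) stop("tol_da must be > 0", call. = FALSE)
  ann <- validate_annotations(annotations)
  ann <- ann[ann$fdr <= max_fdr, , drop = FALSE]
  if (nrow(ann) == 0L)
    stop("no annotations pass the FDR filter (max_fdr = ", max_fdr,
         "); refusing to reduce to an empty peak set", call. = FALSE)
  keep_peak <- function(mz) {
    if (!length(mz)) return(logical(0))
    vapply(mz, function(m) any(abs(m - ann$mz) <= tol_da), logical(1))
  }
  mz_new <- int_new <- vector("list", n_pixels(dataset))
  for (i in seq_len(n_pixels(dataset))) {
    keep <- keep_peak(dataset$mz[[i]])
    mz_new[[i]] <- dataset$mz[[i]][keep]
    int_new[[i]] <- dataset$intensity[[i]][keep]
  }
  msi_dataset(dataset$coords, mz_new, int_new,
              pixel_size = dataset$pixel_size, mode = dataset$mode)
}
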