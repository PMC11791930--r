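## 8-connected component labeling, shared by ROI extraction (PreScan masks)
## and single-cell clustering (DeepScan pixel sets). Diagonal touching merges:
## a cell body sampled on a coarse raster should not be split by a diagonal
## adjacency. Implemented as an iterative stack-based flood fill.

## mask: logical matrix. Returns an integer matrix of the same shape with 0
## for background and components numbered 1..k in raster-scan order of their
## first (top-left-most) pixel.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  # raster-scan order: row-major, top-left first
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(c(r0, c0), ncol = 2)
    lab[r0, c0] <- nxt
    while (nrow(stack)) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      rr <- cur[1] + offs$dr
      cc <- cur[2] + offs$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      rr <- rr[ok]; cc <- cc[ok]
      idx <- cbind(rr, cc)
      new <- mask[idx] & lab[idx] == 0L
      if (any(new)) {
        lab[idx[new, , drop = FALSE]] <- nxt
        stack <- rbind(stack, idx[new, , drop = FALSE])
      }
    }
  }
  lab
}

## Label 8-connected components of a sparse pixel set given as a data.frame
## with 0-based columns x, y. Returns an integer component id per row,
## numbered in raster-scan order.
label_pixel_set <- function(coords) {
  stopifnot(is.data.frame(coords), all(c("x", "y") %in% names(coords)))
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  key <- paste(coords$x, coords$y)
  if (anyDuplicated(key)) stop("pixel coordinates must be unique", call. = FALSE)
  idx_of <- seq_len(n)
  names(idx_of) <- key
  comp <- integer(n)
  # raster-scan order (y major, then x)
  ord <- order(coords$y, coords$x)
  nxt <- 0L
  for (start in ord) {
    if (comp[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    comp[start] <- nxt
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- paste(rep(coords$x[i] + (-1:1), times = 3),
                  rep(coords$y[i] + (-1:1), each = 3))
      hit <- idx_of[nb[nb %in% names(idx_of)]]
      hit <- hit[comp[hit] == 0L]
      if (length(hit)) {
        comp[hit] <- nxt
        stack <- c(stack, hit)
      }
    }
  }
  comp
}
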