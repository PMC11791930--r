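# Independent oracles kept deliberately naive: they re-derive expected
# results by brute force and must never share code with the implementation.

options(prismms.verbose = FALSE)

# Recursive flood fill (8-connectivity) over a logical matrix; returns an
# integer label matrix with components numbered in raster-scan order.
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  fill <- function(r, c, id) {
    queue <- list(c(r, c))
    lab[r, c] <<- id
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- q[1] + dr; cc <- q[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <<- id
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (mask[r, c] && lab[r, c] == 0L) { nxt <- nxt + 1L; fill(r, c, nxt) }
  lab
}

# PAC by explicit double loop over the upper triangle.
oracle_pac <- function(consensus, lower = 0.1, upper = 0.9) {
  n <- nrow(consensus)
  amb <- 0L; tot <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1L
    if (consensus[i, j] > lower && consensus[i, j] < upper) amb <- amb + 1L
  }
  amb / tot
}

# Benjamini-Hochberg step-up by hand: p_(i) * m / i from the largest rank
# down, with a running minimum, capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Tiny processed-mode dataset builder for IO tests.
tiny_dataset <- function(mode = "processed") {
  if (mode == "continuous")
    msi_dataset(data.frame(x = c(0, 1, 2), y = c(0, 0, 1)),
                mz = c(129.0193, 208.1140, 281.2485),
                intensity = list(c(1, 10, 5), c(2, 12, 0), c(0, 9, 7)),
                pixel_size = 20, mode = "continuous")
  else
    msi_dataset(data.frame(x = c(0, 1, 2), y = c(0, 0, 1)),
                mz = list(c(100.1, 200.2), c(150.5, 281.2485), c(129.0193, 300.7)),
                intensity = list(c(1, 2), c(3, 4), c(5, 6)),
                pixel_size = 20, mode = "processed")
}

# Ion image wrapper for threshold tests.
fake_image <- function(grid, pixel_size = 200) {
  structure(list(grid = grid, target_mz = 281.2485, tol = tol_ppm(10),
                 pixel_size = pixel_size), class = "ion_image")
}

mask_of <- function(grid, pixel_size = 200) {
  structure(list(grid = grid, pixel_size = pixel_size, provenance = NULL),
            class = "binary_mask")
}
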