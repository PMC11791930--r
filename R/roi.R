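## ROI extraction: 8-connected components of a binary mask become measurement
## regions whose polygons trace the outer boundary of the component's pixel
## squares. Holes are filled first (a measurement region is a solid area).
## At diagonally-touching pixels the boundary pinches at the shared corner:
## edges never cross, but the corner vertex is visited twice. The trace walks
## with the interior on its left and resolves the pinch by preferring the
## right-most turn, which keeps a diagonal pair inside a single loop.

## Fill holes of a single-component logical mask: background (false) regions
## are 4-connected; any that does not touch the image border is interior.
fill_holes <- function(mask) {
  bg <- EBImage::bwlabel((!mask) * 1)  # bwlabel is 4-connected
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_ids <- setdiff(border_ids, 0)
  mask | (bg > 0 & !(bg %in% border_ids))
}

## Trace the outer boundary of a filled, connected logical mask. Returns an
## n x 2 matrix of grid-vertex coordinates (x = column, y = row, 0-based,
## y increasing downwards), closed (first row repeated last).
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # collect directed edges, interior on the left (y-down frame)
  from <- to <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    if (!at(r - 1, c)) { from <- rbind(from, c(c, r - 1)); to <- rbind(to, c(c - 1, r - 1)) }
    if (!at(r + 1, c)) { from <- rbind(from, c(c - 1, r)); to <- rbind(to, c(c, r)) }
    if (!at(r, c - 1)) { from <- rbind(from, c(c - 1, r - 1)); to <- rbind(to, c(c - 1, r)) }
    if (!at(r, c + 1)) { from <- rbind(from, c(c, r)); to <- rbind(to, c(c, r - 1)) }
  }
  n_edges <- nrow(from)
  used <- logical(n_edges)
  key <- paste(from[, 1], from[, 2])
  out_edges <- split(seq_len(n_edges), key)
  # start at the top edge of the raster-first pixel; its start vertex cannot
  # be a pinch point because no pixel lies above the component's first row
  first <- which(mask, arr.ind = TRUE)
  first <- first[order(first[, 1], first[, 2]), , drop = FALSE][1, ]
  start_edge <- which(from[, 1] == first[2] & from[, 2] == first[1] - 1 &
                      to[, 1] == first[2] - 1)[1]
  path <- from[start_edge, , drop = FALSE]
  cur <- start_edge
  repeat {
    used[cur] <- TRUE
    v <- to[cur, ]
    path <- rbind(path, v)
    if (all(v == from[start_edge, ])) break
    cand <- out_edges[[paste(v[1], v[2])]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) stop("boundary trace failed to close", call. = FALSE)
    if (length(cand) > 1L) {
      # pinch point: prefer the right-most turn to stay in one loop
      d <- v - from[cur, ]
      pref <- rbind(c(-d[2], d[1]), d, c(d[2], -d[1]))  # right, straight, left
      dirs <- to[cand, , drop = FALSE] - matrix(v, length(cand), 2, byrow = TRUE)
      score <- apply(dirs, 1, function(dd)
        which(pref[, 1] == dd[1] & pref[, 2] == dd[2])[1])
      cand <- cand[order(score)][1]
    }
    cur <- cand
  }
  # drop collinear intermediate vertices
  keep <- rep(TRUE, nrow(path))
  for (i in seq(2, nrow(path) - 1L)) {
    a <- path[i, ] - path[i - 1L, ]
    b <- path[i + 1L, ] - path[i, ]
    if (a[1] * b[2] - a[2] * b[1] == 0 && any(a != 0) && any(b != 0))
      keep[i] <- FALSE
  }
  path[keep, , drop = FALSE]
}

#' Extract measurement regions from a binary mask
#'
#' One region per 8-connected component of true cells; each region's polygon
#' is the component's outer boundary (holes filled) converted to stage
#' micrometre through the grid-to-stage transform. Polygons are oriented
#' counter-clockwise; at diagonally-touching pixels the boundary pinches at
#' the shared corner but never self-crosses. Regions are named sequentially
#' (`ROI_001`, ...) in raster-scan order of the component's first pixel.
#'
#' @param mask `binary_mask` with at least one true cell.
#' @param transform 2 x 3 grid-to-stage affine matrix `[A | t]`; defaults to
#'   `pixel_size` times the identity with zero offset.
#' @param name_prefix prefix for sequential region names.
#' @return list of `list(name =, polygon =)` regions (stage micrometre,
#'   closed polygons), suitable for [emit_mis()].
#' @export
extract_rois <- function(mask, transform = NULL, name_prefix = "ROI") {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$grid))
    stop("no cells found: mask has no true pixels (nothing to scan)",
         call. = FALSE)
  if (is.null(transform))
    transform <- cbind(diag(2) * mask$pixel_size, c(0, 0))
  lab <- label_components(mask$grid)
  k <- max(lab)
  regions <- vector("list", k)
  for (i in seq_len(k)) {
    comp <- fill_holes(lab == i)
    verts <- trace_boundary(comp)
    poly <- grid_to_stage(verts, transform)
    if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    regions[[i]] <- list(name = sprintf("%s_%03d", name_prefix, i),
                         polygon = poly)
  }
  regions
}

## Even-odd (ray casting) point-in-polygon test; boundary points count as
## inside. xy: n x 2 points; polygon: closed or open m x 2 matrix.
point_in_polygon <- function(xy, polygon) {
  p <- matrix(as.numeric(polygon), ncol = 2)
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  m <- nrow(p)
  xy <- matrix(as.numeric(xy), ncol = 2)
  vapply(seq_len(nrow(xy)), function(i) {
    x <- xy[i, 1]; y <- xy[i, 2]
    inside <- FALSE
    j <- m
    for (k in seq_len(m)) {
      xi <- p[k, 1]; yi <- p[k, 2]; xj <- p[j, 1]; yj <- p[j, 2]
      # boundary: point on segment
      if ((x - xi) * (yj - yi) == (y - yi) * (xj - xi) &&
          min(xi, xj) <= x && x <= max(xi, xj) &&
          min(yi, yj) <= y && y <= max(yi, yj)) return(TRUE)
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
      j <- k
    }
    inside
  }, logical(1))
}

#' Restrict a dataset to measurement regions
#'
#' Keeps pixels whose stage-coordinate centre falls inside (or on the border
#' of) any region polygon of the document — the in-memory counterpart of a
#' DeepScan acquiring only inside the emitted regions.
#'
#' @param dataset [msi_dataset()].
#' @param document [region_document()] with polygons in stage micrometre.
#' @param transform grid-to-stage 2 x 3 affine for the dataset's own grid;
#'   defaults to `pixel_size` times the identity.
#' @return [msi_dataset()] containing the covered pixels, with `region_id`
#'   set to the first covering region's name.
#' @export
restrict_to_regions <- function(dataset, document, transform = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"),
            inherits(document, "region_document"))
  if (is.null(transform))
    transform <- cbind(diag(2) * dataset$pixel_size, c(0, 0))
  centers <- grid_to_stage(cbind(dataset$coords$x + 0.5,
                                 dataset$coords$y + 0.5), transform)
  hit <- rep(NA_character_, n_pixels(dataset))
  for (r in document$regions) {
    inside <- point_in_polygon(centers, r$polygon)
    hit[is.na(hit) & inside] <- r$name
  }
  keep <- !is.na(hit)
  if (!any(keep))
    stop("no pixels fall inside the document's regions", call. = FALSE)
  coords <- dataset$coords[keep, , drop = FALSE]
  coords$region_id <- hit[keep]
  rownames(coords) <- NULL
  msi_dataset(coords, dataset$mz[keep], dataset$intensity[keep],
              pixel_size = dataset$pixel_size, mode = dataset$mode)
}
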