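## Measurement-region documents (.mis). The vendor schema is proprietary, so
## the package defines a minimal documented XML dialect carrying everything
## the PreScan -> DeepScan hand-off needs; adapting real vendor files means
## writing one translator to/from this dialect.
##
##   <ImagingDocument dialect="prismms-mis-1">
##     <MethodName>deepscan_20um</MethodName>
##     <Raster>20</Raster>                      <!-- step size, micrometre -->
##     <Transform>200 0 0 200 0 0</Transform>   <!-- a11 a12 a21 a22 tx ty -->
##     <Area Name="ROI_001">
##       <Point>0,0</Point>                     <!-- stage x,y micrometre -->
##       ...
##     </Area>
##   </ImagingDocument>
##
## The transform maps grid-vertex coordinates (column, row) to stage
## micrometre: stage = A %*% c(col, row) + t.

#' Measurement-region document
#'
#' Ordered list of measurement regions (polygons in stage micrometre) with a
#' raster step size and acquisition method name — the data model of the
#' `.mis` XML dialect documented in [parse_mis()].
#'
#' @param method_name acquisition method label.
#' @param raster_size raster step in micrometre (> 0).
#' @param regions list of `list(name =, polygon =)` entries; each polygon a
#'   numeric n x 2 matrix of stage coordinates (micrometre). Polygons are
#'   normalized to closed form (first vertex repeated last) and must have at
#'   least 3 distinct vertices. Region names must be unique.
#' @param transform 2 x 3 matrix `[A | t]` mapping grid vertices to stage
#'   micrometre; defaults to `raster_size` times the identity.
#' @return object of class `region_document`.
#' @export
region_document <- function(method_name, raster_size, regions,
                            transform = NULL) {
  stopifnot(is.character(method_name), length(method_name) == 1L)
  if (!is.numeric(raster_size) || length(raster_size) != 1L || raster_size <= 0)
    stop("raster_size must be a positive number (micrometre)", call. = FALSE)
  if (is.null(transform))
    transform <- cbind(diag(2) * raster_size, c(0, 0))
  transform <- matrix(as.numeric(transform), 2, 3)
  stopifnot(is.list(regions))
  regions <- lapply(regions, function(r) {
    stopifnot(!is.null(r$name), !is.null(r$polygon))
    poly <- matrix(as.numeric(r$polygon), ncol = 2)
    # normalize to closed form
    if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
    if (nrow(unique(poly[-nrow(poly), , drop = FALSE])) < 3L)
      stop("integrity error: region '", r$name,
           "' has fewer than 3 distinct vertices", call. = FALSE)
    list(name = as.character(r$name), polygon = poly)
  })
  nms <- vapply(regions, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("integrity error: duplicate region names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  structure(list(method_name = method_name,
                 raster_size = as.numeric(raster_size),
                 regions = regions, transform = transform),
            class = "region_document")
}

#' @export
print.region_document <- function(x, ...) {
  cat(sprintf("<region_document: method '%s', raster %g um, %d region(s)>\n",
              x$method_name, x$raster_size, length(x$regions)))
  for (r in utils::head(x$regions, 5))
    cat(sprintf("  %s: %d vertices, area %.0f um^2\n", r$name,
                nrow(r$polygon) - 1L, abs(polygon_area(r$polygon))))
  if (length(x$regions) > 5) cat("  ...\n")
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a y-up frame.
#'
#' @param polygon n x 2 coordinate matrix (closed or open).
#' @return signed area in squared coordinate units.
#' @export
polygon_area <- function(polygon) {
  p <- matrix(as.numeric(polygon), ncol = 2)
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  i <- seq_len(nrow(p) - 1L)
  sum(p[i, 1] * p[i + 1L, 2] - p[i + 1L, 1] * p[i, 2]) / 2
}

#' Parse a measurement-region document
#'
#' Reads the documented `.mis` XML dialect (see the format comment in the
#' package sources and the methods vignette): root `<ImagingDocument>` with
#' `<MethodName>`, `<Raster>` (micrometre), optional `<Transform>` (6 numbers,
#' `a11 a12 a21 a22 tx ty`) and one `<Area Name=...>` per region holding
#' `<Point>x,y</Point>` stage-coordinate vertices in micrometre.
#'
#' @param path path to the XML file.
#' @return [region_document()].
#' @export
parse_mis <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: malformed XML in ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  root <- xml2::xml_root(doc)
  method <- xml2::xml_find_first(root, ".//MethodName")
  if (inherits(method, "xml_missing"))
    stop("format error: missing <MethodName> element", call. = FALSE)
  raster <- xml2::xml_find_first(root, ".//Raster")
  if (inherits(raster, "xml_missing"))
    stop("format error: missing <Raster> element", call. = FALSE)
  tr <- xml2::xml_find_first(root, ".//Transform")
  transform <- if (inherits(tr, "xml_missing")) NULL else {
    v <- as.numeric(strsplit(trimws(xml2::xml_text(tr)), "\\s+")[[1]])
    if (length(v) != 6L)
      stop("format error: <Transform> must hold 6 numbers", call. = FALSE)
    matrix(v[c(1, 3, 2, 4, 5, 6)], 2, 3)  # stored row-wise a11 a12 a21 a22 tx ty
  }
  areas <- xml2::xml_find_all(root, ".//Area")
  regions <- lapply(areas, function(a) {
    pts <- xml2::xml_text(xml2::xml_find_all(a, ".//Point"))
    xy <- t(vapply(strsplit(pts, ","),
                   function(s) as.numeric(trimws(s)), numeric(2)))
    list(name = xml2::xml_attr(a, "Name"), polygon = xy)
  })
  region_document(method_name = xml2::xml_text(method),
                  raster_size = as.numeric(xml2::xml_text(raster)),
                  regions = regions, transform = transform)
}

#' Emit a measurement-region document
#'
#' Writes a new `.mis`-dialect file for the DeepScan: the template document's
#' fields are preserved except for the method name, raster size and region
#' list, which are replaced — mirroring how the fine-raster acquisition file
#' is derived from the coarse-scan one. Regions appear in input order.
#'
#' @param template [region_document()] the new file is derived from.
#' @param new_regions non-empty region list (as in [region_document()]); a
#'   DeepScan with no target regions is a workflow error, not a file.
#' @param raster_size new raster step in micrometre.
#' @param method_name new acquisition method label.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
emit_mis <- function(template, new_regions, raster_size, method_name, path) {
  stopifnot(inherits(template, "region_document"))
  if (length(new_regions) == 0L)
    stop("refusing to emit a document with no regions (no DeepScan targets)",
         call. = FALSE)
  out <- region_document(method_name = method_name, raster_size = raster_size,
                         regions = new_regions, transform = template$transform)
  write_mis(out, path)
}

#' @rdname emit_mis
#' @param document [region_document()] to serialize as-is.
#' @export
write_mis <- function(document, path) {
  stopifnot(inherits(document, "region_document"))
  doc <- xml2::xml_new_root("ImagingDocument", dialect = "prismms-mis-1")
  xml2::xml_add_child(doc, "MethodName", document$method_name)
  xml2::xml_add_child(doc, "Raster", format(document$raster_size, digits = 15))
  tr <- document$transform
  xml2::xml_add_child(doc, "Transform",
                      paste(format(c(tr[1, 1], tr[1, 2], tr[2, 1], tr[2, 2],
                                     tr[1, 3], tr[2, 3]), digits = 15),
                            collapse = " "))
  for (r in document$regions) {
    a <- xml2::xml_add_child(doc, "Area", Name = r$name)
    for (i in seq_len(nrow(r$polygon)))
      xml2::xml_add_child(a, "Point",
                          paste0(format(r$polygon[i, 1], digits = 15), ",",
                                 format(r$polygon[i, 2], digits = 15)))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## Apply a 2x3 grid->stage transform to an n x 2 matrix of grid coordinates.
grid_to_stage <- function(xy, transform) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  t(transform[, 1:2] %*% t(xy) + transform[, 3])
}
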