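## Minimal imzML 1.1 reader/writer (XML part via xml2, binary ibd via
## readBin/writeBin). Covers what the workflow needs: continuous and
## processed mode, uncompressed 32/64-bit float arrays stored externally in
## the ibd file, UUID linkage between the two files and an MD5 ibd checksum.

IMZML_NS <- "http://psi.hupo.org/ms/mzml"

## Content-derived UUID: the MD5 of the serialized dataset, marked as RFC
## 4122 version 4. Writing the same dataset twice yields byte-identical
## files, which makes synthetic fixtures reproducible from their seed alone.
content_uuid <- function(dataset) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(dataset$coords, dataset$mz, dataset$intensity,
               dataset$pixel_size, dataset$mode), tmp, compress = FALSE)
  h <- unname(tools::md5sum(tmp))
  bytes <- as.raw(strtoi(substring(h, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0F), 0x40))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3F), 0x80))
  bytes
}

uuid_text <- function(bytes) {
  h <- paste(format(bytes), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(h, 1, 8), substr(h, 9, 12),
          substr(h, 13, 16), substr(h, 17, 20), substr(h, 21, 32))
}

precision_bytes <- function(precision) switch(as.character(precision),
  "32" = 4L, "64" = 8L,
  stop("precision must be 32 or 64 (bit float)", call. = FALSE))

ibd_path <- function(imzml_path) sub("\\.imzML$", ".ibd", imzml_path, ignore.case = TRUE)

#' Write an imzML/ibd file pair
#'
#' Emits standard imzML 1.1 with externally stored uncompressed float arrays:
#' the XML index at `path` and the binary payload at the sibling `.ibd` path.
#' The two files are linked by a shared UUID; the ibd MD5 checksum is recorded
#' in the XML. Continuous-mode datasets store the shared m/z axis once.
#'
#' Stored pixel positions are 1-based per the imzML convention; the in-memory
#' 0-based grid coordinates are shifted on write and back-shifted on read.
#'
#' @param dataset [msi_dataset()]; must contain at least one pixel.
#' @param path output path ending in `.imzML`.
#' @param mz_precision,intensity_precision bits per stored float (32 or 64).
#'   The workflow default keeps intensities at 32 bit on disk.
#' @return invisibly, a character vector of the two paths written.
#' @export
write_imzml <- function(dataset, path, mz_precision = 64,
                        intensity_precision = 32) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (n_pixels(dataset) == 0L)
    stop("refusing to write an empty dataset (no pixels)", call. = FALSE)
  if (!grepl("\\.imzML$", path, ignore.case = TRUE))
    stop("path must end in .imzML", call. = FALSE)
  mzb <- precision_bytes(mz_precision)
  inb <- precision_bytes(intensity_precision)
  n <- n_pixels(dataset)
  uuid <- content_uuid(dataset)

  ibd <- ibd_path(path)
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  # per-spectrum external storage bookkeeping (offsets in bytes)
  if (dataset$mode == "continuous") {
    axis <- dataset$mz[[1L]]
    writeBin(axis, con, size = mzb, endian = "little")
    int_len <- lengths(dataset$intensity)
    writeBin(unlist(dataset$intensity, use.names = FALSE), con,
             size = inb, endian = "little")
    mz_off <- rep(16, n); mz_len <- rep(length(axis), n)
    int_off <- 16 + length(axis) * mzb + c(0, cumsum(int_len[-n])) * inb
  } else {
    mz_len <- lengths(dataset$mz)
    int_len <- lengths(dataset$intensity)
    # spectra interleaved: mz block then intensity block per pixel
    starts <- 16 + c(0, cumsum((mz_len * mzb + int_len * inb))[-n])
    mz_off <- starts
    int_off <- starts + mz_len * mzb
    for (i in seq_len(n)) {
      writeBin(as.numeric(dataset$mz[[i]]), con, size = mzb, endian = "little")
      writeBin(as.numeric(dataset$intensity[[i]]), con, size = inb, endian = "little")
    }
  }
  close(con); on.exit(NULL)
  md5 <- unname(tools::md5sum(ibd))

  cv <- function(parent, ref, acc, name, value = NULL, unit = NULL) {
    node <- xml2::xml_add_child(parent, "cvParam", cvRef = ref,
                                accession = acc, name = name)
    if (!is.null(value)) xml2::xml_set_attr(node, "value", as.character(value))
    if (!is.null(unit)) {
      xml2::xml_set_attr(node, "unitCvRef", "UO")
      xml2::xml_set_attr(node, "unitAccession", unit[[1]])
      xml2::xml_set_attr(node, "unitName", unit[[2]])
    }
    node
  }
  doc <- xml2::xml_new_root("mzML", xmlns = IMZML_NS, version = "1.1")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "3")
  xml2::xml_add_child(cvl, "cv", id = "MS", fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology", URI = "http://psidev.info/ms/mzML/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "UO", fullName = "Unit Ontology", URI = "http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo")
  xml2::xml_add_child(cvl, "cv", id = "IMS", fullName = "Imaging MS Ontology", URI = "http://www.maldi-msi.org/download/imzml/imagingMS.obo")
  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  cv(fc, "MS", "MS:1000579", "MS1 spectrum")
  cv(fc, "IMS", paste0("IMS:10000", if (dataset$mode == "continuous") "30" else "31"),
     dataset$mode)
  cv(fc, "IMS", "IMS:1000080", "universally unique identifier", uuid_text(uuid))
  cv(fc, "IMS", "IMS:1000090", "ibd MD5", toupper(md5))
  rpl <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  g1 <- xml2::xml_add_child(rpl, "referenceableParamGroup", id = "mzArray")
  cv(g1, "MS", "MS:1000514", "m/z array")
  cv(g1, "MS", if (mzb == 8L) "MS:1000523" else "MS:1000521",
     paste0(mz_precision, "-bit float"))
  cv(g1, "MS", "MS:1000576", "no compression")
  cv(g1, "IMS", "IMS:1000101", "external data", "true")
  g2 <- xml2::xml_add_child(rpl, "referenceableParamGroup", id = "intensityArray")
  cv(g2, "MS", "MS:1000515", "intensity array")
  cv(g2, "MS", if (inb == 8L) "MS:1000523" else "MS:1000521",
     paste0(intensity_precision, "-bit float"))
  cv(g2, "MS", "MS:1000576", "no compression")
  cv(g2, "IMS", "IMS:1000101", "external data", "true")
  sw <- xml2::xml_add_child(doc, "softwareList", count = "1")
  xml2::xml_add_child(sw, "software", id = "prismms",
                      version = as.character(utils::packageVersion("prismms")))
  ssl <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  ss <- xml2::xml_add_child(ssl, "scanSettings", id = "scanSettings1")
  cv(ss, "IMS", "IMS:1000042", "max count of pixels x", max(dataset$coords$x) + 1L)
  cv(ss, "IMS", "IMS:1000043", "max count of pixels y", max(dataset$coords$y) + 1L)
  cv(ss, "IMS", "IMS:1000046", "pixel size (x)", dataset$pixel_size,
     unit = c("UO:0000017", "micrometer"))
  cv(ss, "IMS", "IMS:1000047", "pixel size y", dataset$pixel_size,
     unit = c("UO:0000017", "micrometer"))
  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")
  dpl <- xml2::xml_add_child(doc, "dataProcessingList", count = "1")
  dp <- xml2::xml_add_child(dpl, "dataProcessing", id = "dp1")
  pm <- xml2::xml_add_child(dp, "processingMethod", order = "1", softwareRef = "prismms")
  cv(pm, "MS", "MS:1000544", "Conversion to mzML")
  run <- xml2::xml_add_child(doc, "run", defaultInstrumentConfigurationRef = "IC1",
                             id = "run1")
  xml2::xml_add_child(run, "spectrumList", count = as.character(n),
                      defaultDataProcessingRef = "dp1")

  # The header is built with xml2; the (possibly very long) spectrum list is
  # generated as text and spliced in, which is orders of magnitude faster
  # than growing an XML tree node by node.
  header <- as.character(doc)
  # reopen the self-closed spectrumList and drop the closing run/mzML tags
  header <- sub("/>[[:space:]]*</run>[[:space:]]*</mzML>[[:space:]]*$", ">",
                header)
  spectra <- sprintf(paste(
    '    <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
    '      <scanList count="1">',
    '        <scan instrumentConfigurationRef="IC1">',
    '          <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
    '        </scan>',
    '      </scanList>',
    '      <binaryDataArrayList count="2">',
    '        <binaryDataArray encodedLength="0">',
    '          <referenceableParamGroupRef ref="mzArray"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '          <binary/>',
    '        </binaryDataArray>',
    '        <binaryDataArray encodedLength="0">',
    '          <referenceableParamGroupRef ref="intensityArray"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
    '          <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '          <binary/>',
    '        </binaryDataArray>',
    '      </binaryDataArrayList>',
    '    </spectrum>', sep = "\n"),
    seq_len(n) - 1L, seq_len(n), int_len,
    dataset$coords$x + 1L, dataset$coords$y + 1L,
    mz_len, mz_len * mzb, mz_off,
    int_len, int_len * inb, int_off)
  out_con <- file(path, "wb")  # binary mode: LF line endings on any platform
  writeLines(c(header, spectra, "  </spectrumList>", "</run>", "</mzML>"),
             out_con, sep = "\n")
  close(out_con)
  invisible(c(path, ibd))
}

param_value <- function(node, accession, required = TRUE, where = "",
                        p = "", ns = character()) {
  hit <- xml2::xml_find_first(
    node, sprintf(".//%scvParam[@accession='%s']", p, accession), ns)
  if (inherits(hit, "xml_missing")) {
    if (required)
      stop("format error: missing cvParam ", accession, " ", where, call. = FALSE)
    return(NA_character_)
  }
  xml2::xml_attr(hit, "value")
}

group_precision <- function(group_node, p = "", ns = character()) {
  has <- function(acc) !inherits(xml2::xml_find_first(
    group_node, sprintf(".//%scvParam[@accession='%s']", p, acc), ns),
    "xml_missing")
  if (has("MS:1000523")) return(8L)
  if (has("MS:1000521")) return(4L)
  stop("format error: array precision not declared (expect 32- or 64-bit float) ",
       "in referenceableParamGroup ", xml2::xml_attr(group_node, "id"), call. = FALSE)
}

#' Read an imzML/ibd file pair
#'
#' Parses the XML index and loads every pixel spectrum from the binary ibd
#' file. The UUID stored in both files must agree; an ibd MD5 checksum, if
#' present, is verified. Duplicate pixel coordinates raise an integrity
#' error. `mz_tolerance_ppm` is attached to the returned dataset as the
#' default alignment tolerance for [common_axis()]/[pixel_matrix()].
#'
#' @param path path to the `.imzML` file (the `.ibd` sibling must exist).
#' @param mz_tolerance_ppm read-time peak alignment tolerance in ppm.
#' @param check_md5 verify the ibd checksum (default TRUE).
#' @return [msi_dataset()] with attribute `tol` ([tol_ppm()]).
#' @export
read_imzml <- function(path, mz_tolerance_ppm = 10, check_md5 = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ibd <- ibd_path(path)
  if (!file.exists(ibd)) stop("missing binary file: ", ibd, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: malformed XML in ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  # Namespace-prefixed absolute xpaths: stripping namespaces from a large
  # document is quadratic in libxml2, prefixing is not.
  ns <- xml2::xml_ns(doc)
  p <- if ("d1" %in% names(ns)) "d1:" else ""
  root <- sprintf("/%s%s", p, xml2::xml_name(xml2::xml_root(doc)))
  fc <- xml2::xml_find_first(
    doc, sprintf("%s/%sfileDescription/%sfileContent", root, p, p), ns)
  if (inherits(fc, "xml_missing"))
    stop("format error: missing <fileContent> element", call. = FALSE)
  has_fc <- function(acc) !inherits(xml2::xml_find_first(
    fc, sprintf(".//%scvParam[@accession='%s']", p, acc), ns), "xml_missing")
  mode <- if (has_fc("IMS:1000030")) "continuous"
          else if (has_fc("IMS:1000031")) "processed"
          else stop("format error: neither continuous nor processed mode declared in <fileContent>",
                    call. = FALSE)
  uuid_xml <- param_value(fc, "IMS:1000080", where = "in <fileContent>",
                          p = p, ns = ns)
  md5_xml <- param_value(fc, "IMS:1000090", required = FALSE, p = p, ns = ns)
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuid_ibd <- readBin(con, "raw", 16L)
  if (gsub("[{}-]", "", tolower(uuid_xml)) != paste(format(uuid_ibd), collapse = ""))
    stop("integrity error: UUID mismatch between imzML and ibd", call. = FALSE)
  if (check_md5 && !is.na(md5_xml) &&
      tolower(md5_xml) != tolower(unname(tools::md5sum(ibd))))
    stop("integrity error: ibd MD5 checksum mismatch", call. = FALSE)

  groups <- xml2::xml_find_all(
    doc, sprintf("%s/%sreferenceableParamGroupList/%sreferenceableParamGroup",
                 root, p, p), ns)
  gid <- xml2::xml_attr(groups, "id")
  mz_group <- int_group <- NA_character_
  prec <- list()
  has_in <- function(node, acc) !inherits(xml2::xml_find_first(
    node, sprintf(".//%scvParam[@accession='%s']", p, acc), ns), "xml_missing")
  for (i in seq_along(groups)) {
    if (has_in(groups[[i]], "MS:1000514")) mz_group <- gid[i]
    if (has_in(groups[[i]], "MS:1000515")) int_group <- gid[i]
    prec[[gid[i]]] <- group_precision(groups[[i]], p, ns)
  }
  if (is.na(mz_group) || is.na(int_group))
    stop("format error: m/z / intensity referenceableParamGroup not found", call. = FALSE)

  px <- xml2::xml_attr(xml2::xml_find_first(
    doc, sprintf("%s/%sscanSettingsList/%sscanSettings/%scvParam[@accession='IMS:1000046']",
                 root, p, p, p), ns), "value")
  pixel_size <- if (is.na(px)) 1 else as.numeric(px)

  spectrum_path <- sprintf("%s/%srun/%sspectrumList/%sspectrum", root, p, p, p)
  n <- length(xml2::xml_find_all(doc, spectrum_path, ns))
  if (n == 0L) stop("format error: no <spectrum> elements", call. = FALSE)

  # All per-spectrum metadata is pulled with document-order global queries
  # (one absolute xpath each) rather than per-node lookups, which keeps
  # large images fast. Every spectrum must carry one position x/y and two
  # external binaryDataArrays tagged by referenceableParamGroupRef.
  grab <- function(xpath, what, expected) {
    v <- xml2::xml_attr(xml2::xml_find_all(doc, xpath, ns), "value")
    if (length(v) != expected)
      stop("format error: expected ", expected, " ", what, " entries, found ",
           length(v), call. = FALSE)
    v
  }
  scan_path <- sprintf("%s/%sscanList/%sscan/%scvParam", spectrum_path, p, p, p)
  arr_path <- sprintf("%s/%sbinaryDataArrayList/%sbinaryDataArray",
                      spectrum_path, p, p)
  xs <- as.integer(grab(sprintf("%s[@accession='IMS:1000050']", scan_path),
                        "position x", n)) - 1L
  ys <- as.integer(grab(sprintf("%s[@accession='IMS:1000051']", scan_path),
                        "position y", n)) - 1L
  refs <- xml2::xml_attr(xml2::xml_find_all(
    doc, sprintf("%s/%sreferenceableParamGroupRef", arr_path, p), ns), "ref")
  offs <- as.numeric(grab(
    sprintf("%s/%scvParam[@accession='IMS:1000102']", arr_path, p),
    "external offset", 2L * n))
  lens <- as.integer(grab(
    sprintf("%s/%scvParam[@accession='IMS:1000103']", arr_path, p),
    "external array length", 2L * n))
  if (length(refs) != 2L * n)
    stop("format error: every binaryDataArray needs a referenceableParamGroupRef",
         call. = FALSE)
  is_mz_arr <- refs == mz_group

  read_array <- function(offset, len, bytes) {
    seek(con, where = offset, origin = "start")
    readBin(con, "numeric", n = len, size = bytes, endian = "little")
  }
  mz_list <- int_list <- vector("list", n)
  spec_idx <- rep(seq_len(n), each = 2L)
  mz_bytes <- prec[[mz_group]]; int_bytes <- prec[[int_group]]
  shared_axis <- NULL
  for (j in seq_along(refs)) {
    i <- spec_idx[j]
    if (is_mz_arr[j]) {
      if (mode == "continuous") {
        if (is.null(shared_axis))
          shared_axis <- read_array(offs[j], lens[j], mz_bytes)
        mz_list[[i]] <- shared_axis
      } else mz_list[[i]] <- read_array(offs[j], lens[j], mz_bytes)
    } else {
      int_list[[i]] <- read_array(offs[j], lens[j], int_bytes)
    }
  }
  out <- msi_dataset(data.frame(x = xs, y = ys), mz_list, int_list,
                     pixel_size = pixel_size, mode = mode)
  attr(out, "tol") <- tol_ppm(mz_tolerance_ppm)
  out
}
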