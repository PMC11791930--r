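Package: prismms
Title: Mass-Guided Two-Pass MALDI Imaging for Single-Cell Low-Mass
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a mass-guided two-pass MALDI mass spectrometry
    imaging (MSI) workflow for single-cell metabolomics of low-mass
    (<200 Da) compounds: a coarse PreScan is thresholded on a cell-marker
    ion image to emit measurement regions for a fine DeepScan; DeepScan
    pixels are normalized to an internal standard (or total ion current),
    z-standardized, and clustered into single-cell objects; Monte Carlo
    reference-based consensus clustering decides per feature whether the
    cell population splits into subpopulations; and Cohen's D effect-size
    volcano statistics with Benjamini-Hochberg control compare groups.
    Includes a minimal imzML 1.1 reader/writer, a documented XML dialect
    for measurement-region documents, exact monoisotopic mass and adduct
    m/z calculation with heavy-isotope labels, and a synthetic
    ground-truth field generator (giant unilamellar vesicle mixtures and
    activation experiments) so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
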