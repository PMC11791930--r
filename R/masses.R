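## Monoisotopic masses of the most abundant isotope per element, plus the
## heavy isotopes used for internal-standard labelling. Values from the
## CODATA/AME2020 atomic mass evaluation (IUPAC Technical Report 2021),
## truncated well below the 0.0001 Da precision used anywhere downstream.
ISOTOPE_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  # heavy labels (symbol = conventional shorthand, e.g. D = 2H)
  D       = 2.01410177785,
  `13C`   = 13.0033548378,
  `15N`   = 15.0001088989
)

## Which light element a heavy label substitutes.
LABEL_PARENT <- c(D = "H", `13C` = "C", `15N` = "N")

PROTON_MASS <- 1.007276466  # m(1H) - m(e-)
SODIUM_CATION_MASS <- 22.989218      # m(Na) - m(e-)

#' Parse an elemental formula
#'
#' Accepts Hill-notation formula strings with an explicit heavy-isotope label
#' syntax: deuterium either as the `D` shorthand (`"C11H7D5N2O2"`) or as a
#' bracketed prefix count (`"[2H5]C11H7N2O2"`, also `[13C6]`, `[15N2]`).
#' Nested groups/parentheses are not supported.
#'
#' @param formula formula string.
#' @return named integer vector of element (and label) counts, class
#'   `prism_formula`.
#' @examples
#' parse_formula("C11H7D5N2O2")  # tryptophan-d5
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  counts <- integer(0)
  add <- function(sym, n) {
    counts[sym] <<- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  rest <- formula
  # bracketed isotope labels, e.g. [2H5], [13C6]
  while (grepl("^\\[", rest)) {
    m <- regmatches(rest, regexec("^\\[(1[35]|2)([A-Z][a-z]?)([0-9]*)\\]", rest))[[1]]
    if (length(m) == 0) stop("malformed isotope label in formula: ", formula, call. = FALSE)
    iso <- paste0(m[2], m[3])
    sym <- switch(iso, "2H" = "D", "13C" = "13C", "15N" = "15N",
                  stop("unsupported isotope label: [", iso, "]", call. = FALSE))
    add(sym, if (nzchar(m[4])) as.integer(m[4]) else 1L)
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0 || !nzchar(m[1]))
      stop("cannot parse formula near '", rest, "' in: ", formula, call. = FALSE)
    add(m[2], if (nzchar(m[3])) as.integer(m[3]) else 1L)
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  unknown <- setdiff(names(counts), names(ISOTOPE_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  structure(counts, class = "prism_formula")
}

as_formula <- function(x) {
  if (inherits(x, "prism_formula")) x else parse_formula(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope masses, with labelled positions (D, 13C, 15N)
#' carrying their heavy-isotope mass. Labels are *additional* atoms in the
#' count vector, i.e. `"C11H7D5N2O2"` has 7 light H and 5 D.
#'
#' @param formula formula string or result of [parse_formula()].
#' @return monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")            # 18.0106
#' monoisotopic_mass("C11H7D5N2O2")    # tryptophan-d5, 209.1213
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  sum(ISOTOPE_MASS[names(f)] * as.numeric(f))
}

SUPPORTED_ADDUCTS <- c("[M+H]+", "[M-H]-", "[M+Na]+")

#' Adduct m/z
#'
#' Exact m/z of a singly charged adduct. Arithmetic is electron-corrected:
#' protonation/deprotonation uses the proton mass 1.007276 Da (not neutral H),
#' sodiation the Na+ cation mass 22.989218 Da, which reproduces 4-decimal
#' instrument calibrant values.
#'
#' @param formula formula string or [parse_formula()] result.
#' @param adduct one of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"` (unicode minus
#'   accepted).
#' @return m/z in Da.
#' @examples
#' adduct_mz("C10H10N2", "[M-H]-")      # 1,5-diaminonaphthalene, 157.0771
#' adduct_mz("C11H7D5N2O2", "[M-H]-")   # Trp-d5 internal standard, 208.1140
#' adduct_mz("C44H84NO8P", "[M+H]+")    # DOPC, 786.6
#' @export
adduct_mz <- function(formula, adduct) {
  f <- as_formula(formula)
  adduct <- gsub("−|‐|‑|–", "-", adduct)  # unicode dashes
  if (!adduct %in% SUPPORTED_ADDUCTS)
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(SUPPORTED_ADDUCTS, collapse = ", "), call. = FALSE)
  M <- monoisotopic_mass(f)
  switch(adduct,
    "[M+H]+" = M + PROTON_MASS,
    "[M-H]-" = {
      nH <- sum(as.numeric(f[names(f) %in% c("H", "D")]))
      if (nH < 1) stop("cannot deprotonate a formula with no hydrogen", call. = FALSE)
      M - PROTON_MASS
    },
    "[M+Na]+" = M + SODIUM_CATION_MASS
  )
}

#' Match an observed m/z against annotation candidates
#'
#' Returns the nearest candidate within tolerance; ties on |delta m/z| are
#' broken by lower FDR.
#'
#' @param observed observed m/z (Da).
#' @param candidates annotation table (data.frame with columns `formula`,
#'   `adduct`, `mz`, `fdr`), see [read_annotations()].
#' @param tol [tol_ppm()] or [tol_da()] tolerance.
#' @return one-row data.frame (the best candidate) or `NULL` if none matches.
#' @export
match_mz <- function(observed, candidates, tol) {
  stopifnot(is.numeric(observed), length(observed) == 1L)
  candidates <- validate_annotations(candidates)
  # window defined around each candidate m/z
  hit <- mz_within(rep(observed, nrow(candidates)), candidates$mz, tol)
  if (!any(hit)) return(NULL)
  cand <- candidates[hit, , drop = FALSE]
  delta <- abs(observed - cand$mz)
  cand <- cand[order(delta, cand$fdr), , drop = FALSE]
  cand[1L, , drop = FALSE]
}
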