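# Monoisotopic mass arithmetic for small-molecule formulas.
#
# Masses of the most abundant isotopes (CODATA/IUPAC values, Da).  Only the
# elements that occur in the packaged catalog plus a few common hetero atoms
# are tabulated; parse_formula() rejects anything else.

.element_masses <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#' Mass of a proton in Da
#'
#' Used for deprotonated-ion arithmetic; the electron mass is neglected so
#' that \eqn{[M-H]^- = M - m_p}.
#' @keywords internal
PROTON_MASS <- 1.00727646

#' Monoisotopic mass of formic acid (HCOOH), Da
#' @keywords internal
FORMIC_ACID_MASS <- 46.00548

#' Parse a molecular formula string
#'
#' Parses a flattened Hill-style formula such as `"C42H72O14"` into a named
#' vector of element counts.  A bare element symbol means count 1
#' (`"H2O"` gives `c(H = 2, O = 1)`).
#'
#' @param text Formula string; element symbols (one capital letter plus an
#'   optional lower-case letter) each followed by an optional integer count.
#' @return Named integer vector of element counts, class `"molecular_formula"`.
#' @examples
#' parse_formula("C42H72O14")
#' parse_formula("C15H21NO7")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse formula: ", text)
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  cnt[is.na(cnt)] <- 1L
  bad <- setdiff(sym, names(.element_masses))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(cnt < 1L)) stop("element counts must be >= 1")
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  class(out) <- "molecular_formula"
  out
}

#' Render a formula back to text
#'
#' Inverse of [parse_formula()]: element symbols in the stored order with
#' counts, count 1 written bare.
#' @param f A `molecular_formula` (or named count vector).
#' @return A single string.
#' @export
format_formula <- function(f) {
  stopifnot(length(f) >= 1L, !is.null(names(f)))
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times atomic monoisotopic mass over the elements present.
#'
#' @param f A `molecular_formula`, named count vector, or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C42H72O14")  # 800.49221
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (is.null(names(f)) || length(f) < 1L)
    stop("need a named element-count vector")
  bad <- setdiff(names(f), names(.element_masses))
  if (length(bad))
    stop("no tabulated monoisotopic mass for: ", paste(bad, collapse = ", "))
  sum(unclass(f) * .element_masses[names(f)])
}

#' Negative-mode adduct ion m/z
#'
#' Converts a neutral monoisotopic mass to the m/z of a negative-mode ion.
#' The deprotonated ion is `M - 1.00727646` (proton mass; the electron mass
#' is neglected) and the formate adduct is `M + 46.00548 - 1.00727646`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da, > 0.
#' @param adduct `"[M-H]-"` or `"[M-H+FA]-"`.
#' @return Ion m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct = c("[M-H]-", "[M-H+FA]-")) {
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("neutral_mass must be positive")
  adduct <- match.arg(adduct)
  switch(adduct,
    "[M-H]-"    = neutral_mass - PROTON_MASS,
    "[M-H+FA]-" = neutral_mass + FORMIC_ACID_MASS - PROTON_MASS
  )
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da), > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`, signed.
#' @export
ppm_error <- function(observed, theoretical) {
  if (!is.numeric(theoretical) || any(theoretical <= 0))
    stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

# Round half away from zero, the convention used for printed ppm columns
# (base round() rounds half to even).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
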