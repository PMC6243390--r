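# LC-HRMS compound catalog: loading, mass validation, fragment annotation.

#' Neutral-loss library for negative-mode glycoside fragmentation
#'
#' Monoisotopic masses (Da) of the neutral losses commonly seen in MS/MS of
#' plant glycosides: anhydro-hexose (Glc), anhydro-deoxyhexose (Rha),
#' anhydro-pentose (Xyl and Api are isomeric and share one mass class),
#' water, carbon dioxide, formaldehyde, and formic acid.
#' @export
neutral_losses <- c(
  Glc  = 162.05282,
  Rha  = 146.05791,
  "Xyl/Api" = 132.04226,
  H2O  = 18.01056,
  CO2  = 43.98983,
  CH2O = 30.01057,
  FA   = 46.00548
)

#' Load a compound catalog CSV
#'
#' Reads a table of chromatographic/mass-spectral records, one row per
#' chromatographic peak.  Required columns: `peak_no`, `tr_min`, `name`,
#' `detected_mz`, `formula`, `error_ppm`, `fragments`, `source`.  The
#' `fragments` column encodes MS/MS ions as semicolon-separated `"mz|label"`
#' pairs; `error_ppm` may be empty where the original table prints none.
#' Unidentified rows keep the name `"Unknown"`.
#'
#' @param path Path to the CSV file.  The default is the packaged catalog of
#'   71 constituents of the Wenxin Keli (WXKL) extract.
#' @return A data.frame of class `"compound_catalog"` with list-column
#'   `fragments` (each element a data.frame with `mz` and `label`).
#' @export
load_catalog <- function(path = system.file("extdata", "wxkl_catalog.csv",
                                            package = "cardioscreen")) {
  if (!nzchar(path) || !file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("catalog file is empty")
  required <- c("peak_no", "tr_min", "name", "detected_mz", "formula",
                "error_ppm", "fragments", "source")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("name", "formula", "fragments", "source")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  if (anyDuplicated(df$peak_no))
    stop("duplicate peak_no in catalog: ",
         paste(unique(df$peak_no[duplicated(df$peak_no)]), collapse = ", "))
  if (any(df$detected_mz <= 0)) stop("detected_mz must be positive")
  df$fragments <- lapply(df$fragments, .parse_fragment_field)
  class(df) <- c("compound_catalog", "data.frame")
  df
}

.parse_fragment_field <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(mz = numeric(0), label = character(0)))
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  data.frame(
    mz = as.numeric(vapply(parts, `[`, "", 1L)),
    label = vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' Recompute catalog mass errors and check them against the printed values
#'
#' For every record carrying a molecular formula, computes the theoretical
#' m/z under the candidate negative-mode adducts (deprotonated ion first,
#' then the formate adduct), selects the first adduct within `search_ppm` of
#' the detected m/z, and compares the recomputed signed ppm error (rounded
#' half away from zero to `ppm_round` decimals) with the printed one.
#'
#' Status per row: `"verified"` (recomputed equals printed to the rounding
#' tolerance), `"mismatch"` (an adduct matches but the printed error
#' differs), `"unverifiable"` (no formula, no printed numeric error, or no
#' adduct within the search window -- i.e. the printed formula is
#' inconsistent with the detected mass).
#'
#' @param catalog A `compound_catalog` from [load_catalog()].
#' @param ppm_round Decimals used when rounding recomputed ppm (default 1).
#' @param search_ppm Adduct search window in ppm (default 20).
#' @return Data.frame (class `"catalog_validation"`): `peak_no`, `name`,
#'   `adduct`, `theoretical_mz`, `recomputed_ppm`, `printed_ppm`, `status`.
#' @export
validate_catalog <- function(catalog, ppm_round = 1, search_ppm = 20) {
  stopifnot(inherits(catalog, "compound_catalog"))
  adducts <- c("[M-H]-", "[M-H+FA]-")
  out <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- catalog[i, ]
    printed <- suppressWarnings(as.numeric(rec$error_ppm))
    row <- data.frame(peak_no = rec$peak_no, name = rec$name,
                      adduct = NA_character_, theoretical_mz = NA_real_,
                      recomputed_ppm = NA_real_, printed_ppm = printed,
                      status = "unverifiable", stringsAsFactors = FALSE)
    if (is.na(rec$formula) || !nzchar(rec$formula)) return(row)
    mass <- tryCatch(monoisotopic_mass(rec$formula), error = function(e) NA)
    if (is.na(mass)) return(row)
    for (ad in adducts) {
      th <- adduct_mz(mass, ad)
      ppm <- ppm_error(rec$detected_mz, th)
      if (abs(ppm) <= search_ppm) {
        row$adduct <- ad
        row$theoretical_mz <- th
        row$recomputed_ppm <- round_half_away(ppm, ppm_round)
        row$status <- if (!is.na(printed) &&
                          abs(row$recomputed_ppm - printed) <= 0.05)
          "verified" else "mismatch"
        break
      }
    }
    row
  })
  res <- do.call(rbind, out)
  class(res) <- c("catalog_validation", "data.frame")
  res
}

#' Write a catalog validation report to CSV
#'
#' @param report A `catalog_validation` from [validate_catalog()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "catalog_validation"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Annotate an MS/MS fragment by neutral-loss combinations
#'
#' Searches for the smallest multiset of losses from [neutral_losses]
#' (each usable more than once) such that the deprotonated precursor minus
#' the summed losses matches `fragment_mz` within `tol`.  Ties in multiset
#' size are broken by the smallest absolute mass deviation.
#'
#' @param precursor Precursor molecular formula (string, parsed vector, or
#'   `molecular_formula`).
#' @param fragment_mz Observed fragment m/z (Da).
#' @param max_losses Maximum number of losses to combine (default 3).
#' @param tol Absolute matching tolerance in Da (default 0.02; printed
#'   fragment masses can deviate ~10 ppm from exact loss arithmetic).
#' @return List of class `"fragment_annotation"`: `fragment_mz`,
#'   `loss_composition` (character vector of loss names, possibly repeated),
#'   `theoretical_mz`, `delta_da`, `matched`.
#' @export
annotate_fragment <- function(precursor, fragment_mz, max_losses = 3,
                              tol = 0.02) {
  mz0 <- adduct_mz(monoisotopic_mass(precursor), "[M-H]-")
  best <- NULL
  nms <- names(neutral_losses)
  k <- length(nms)
  # multisets of size 0..max_losses, generated by non-decreasing index tuples
  grow <- function(idx, lo) {
    th <- mz0 - sum(neutral_losses[idx])
    delta <- th - fragment_mz
    if (abs(delta) <= tol) {
      cand <- list(losses = nms[idx], theoretical = th, delta = delta)
      if (is.null(best) ||
          length(cand$losses) < length(best$losses) ||
          (length(cand$losses) == length(best$losses) &&
           abs(cand$delta) < abs(best$delta)))
        best <<- cand
    }
    if (length(idx) < max_losses)
      for (j in lo:k) grow(c(idx, j), j)
  }
  grow(integer(0), 1L)
  structure(list(
    fragment_mz = fragment_mz,
    loss_composition = if (is.null(best)) character(0) else best$losses,
    theoretical_mz = if (is.null(best)) NA_real_ else best$theoretical,
    delta_da = if (is.null(best)) NA_real_ else best$delta,
    matched = !is.null(best)
  ), class = "fragment_annotation")
}

#' Known discrepancies of the packaged catalog
#'
#' Rows of the packaged WXKL catalog where the printed name, formula, and
#' detected mass are mutually inconsistent, recorded as printed rather than
#' silently corrected.
#'
#' @param path Sidecar CSV path (default: packaged file).
#' @return Data.frame with `peak_no` and `issue`.
#' @export
known_discrepancies <- function(path = system.file(
    "extdata", "wxkl_catalog_discrepancies.csv", package = "cardioscreen")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
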