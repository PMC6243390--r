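# Activity-index scoring: combine a fraction x compound peak-area matrix
# with per-fraction bioactivity coefficients into per-compound scores.
#
# The score of compound j is AI_j = sum_i R_i * A_ij / sum_i A_ij -- an
# abundance-weighted mean of the fraction recovery rates, so a compound
# concentrated in active fractions inherits their activity.

#' Normalise a peak-area matrix per compound
#'
#' Divides each entry by its compound's (column) total across fractions so
#' every retained column sums to one.  Compounds absent from every fraction
#' cannot be normalised and are dropped with a warning (an AI of 0 would
#' masquerade as "neutral").
#'
#' @param areas Non-negative matrix, fractions as rows (named), compounds
#'   as columns (named).
#' @return Column-stochastic matrix; dropped compound ids in attribute
#'   `"dropped"`.
#' @export
normalize_areas <- function(areas) {
  if (!is.matrix(areas) || any(areas < 0))
    stop("areas must be a non-negative matrix")
  tot <- colSums(areas)
  if (all(tot == 0)) stop("all compound columns are zero")
  drop <- tot == 0
  if (any(drop)) {
    warning("dropping compound(s) absent from every fraction: ",
            paste(colnames(areas)[drop], collapse = ", "))
    areas <- areas[, !drop, drop = FALSE]
    tot <- tot[!drop]
  }
  out <- sweep(areas, 2, tot, "/")
  attr(out, "dropped") <- names(drop)[drop]
  out
}

#' Activity indexes of compounds
#'
#' `AI_j = sum_i R_i * A_ij` over the normalised abundance shares `A_ij`;
#' compounds with a positive AI are candidate actives.
#'
#' @param norm_areas Column-stochastic matrix from [normalize_areas()].
#' @param recovery Named per-fraction coefficient vector (percent), covering
#'   every row of `norm_areas`.  Usually heart-rate recovery rates
#'   ([recovery_rate()]); any per-fraction bioactivity coefficient (e.g.
#'   cell protection rates) can be used.
#' @return Data.frame of class `"activity_scores"`: `compound`, `ai`,
#'   `rank` (1 = highest AI, ties broken by compound id), `positive`.
#' @export
activity_indexes <- function(norm_areas, recovery) {
  missing <- setdiff(rownames(norm_areas), names(recovery))
  if (length(missing))
    stop("recovery vector missing fraction(s): ",
         paste(missing, collapse = ", "))
  r <- recovery[rownames(norm_areas)]
  ai <- as.numeric(crossprod(norm_areas, r))
  out <- data.frame(compound = colnames(norm_areas), ai = ai,
                    stringsAsFactors = FALSE)
  ord <- order(-out$ai, out$compound)
  out$rank[ord] <- seq_len(nrow(out))
  out$positive <- out$ai > 0
  class(out) <- c("activity_scores", "data.frame")
  out
}

#' Rank compounds by activity index
#'
#' @param scores An `"activity_scores"` data.frame.
#' @return The same rows ordered by descending AI (ties by compound id).
#' @export
rank_compounds <- function(scores) {
  stopifnot(inherits(scores, "activity_scores"), nrow(scores) > 0)
  out <- scores[order(scores$rank), ]
  rownames(out) <- NULL
  out
}

#' Bio-active map
#'
#' Entry (i, j) is `R_i * A_ij`: the content heatmap reweighted by each
#' fraction's bioactivity coefficient, so that column sums equal the
#' compound activity indexes.
#'
#' @inheritParams activity_indexes
#' @return Matrix of the same shape as `norm_areas`.
#' @export
bioactive_map <- function(norm_areas, recovery) {
  missing <- setdiff(rownames(norm_areas), names(recovery))
  if (length(missing))
    stop("recovery vector missing fraction(s): ",
         paste(missing, collapse = ", "))
  sweep(norm_areas, 1, recovery[rownames(norm_areas)], "*")
}

#' Dual-assay score coordinates
#'
#' Joins the zebrafish heart-rate AI (y) with a cell-protection AI (x)
#' computed by the same weighted-mean machinery; compounds in the upper
#' right of the (x, y) plane are active in both assays.
#'
#' @param ai_zebrafish `"activity_scores"` from the heart-rate recovery
#'   coefficients.
#' @param ai_cell `"activity_scores"` from the cell-protection
#'   coefficients.
#' @return Data.frame `compound`, `cell_ai` (x), `zebrafish_ai` (y);
#'   compounds present in only one input are reported in attribute
#'   `"unmatched"`.
#' @export
dual_scores <- function(ai_zebrafish, ai_cell) {
  stopifnot(inherits(ai_zebrafish, "activity_scores"),
            inherits(ai_cell, "activity_scores"))
  shared <- intersect(ai_zebrafish$compound, ai_cell$compound)
  if (!length(shared)) stop("no shared compounds between the two assays")
  out <- data.frame(
    compound = shared,
    cell_ai = ai_cell$ai[match(shared, ai_cell$compound)],
    zebrafish_ai = ai_zebrafish$ai[match(shared, ai_zebrafish$compound)],
    stringsAsFactors = FALSE
  )
  attr(out, "unmatched") <- setdiff(
    union(ai_zebrafish$compound, ai_cell$compound), shared)
  out
}
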