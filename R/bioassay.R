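# Bioassay statistics: MTT viability rates, heart-rate recovery, summaries.

#' MTT survival rate
#'
#' `100 * OD_tested / OD_control`, in percent.
#'
#' @param od_tested_mean Mean OD of the treated group.
#' @param od_control_mean Mean OD of the untreated control, > 0.
#' @return Survival rate in percent (vectorised over `od_tested_mean`).
#' @export
survival_rate <- function(od_tested_mean, od_control_mean) {
  if (!is.numeric(od_control_mean) || od_control_mean <= 0)
    stop("control OD must be positive")
  100 * od_tested_mean / od_control_mean
}

#' MTT protection rate
#'
#' `100 * (OD_model - OD_tested) / (OD_model - OD_control)`: 100% when the
#' treatment restores the control OD, 0% when it leaves the injured
#' (model) OD unchanged.  Not clamped; treatments worse than the injury
#' give negative values.
#'
#' @param od_tested_mean Mean OD of the treated group.
#' @param od_model_mean Mean OD of the injured (model) group.
#' @param od_control_mean Mean OD of the untreated control.
#' @return Protection rate in percent (vectorised over `od_tested_mean`).
#' @export
protection_rate <- function(od_tested_mean, od_model_mean, od_control_mean) {
  if (od_model_mean == od_control_mean)
    stop("protection rate undefined when model OD equals control OD")
  100 * (od_model_mean - od_tested_mean) / (od_model_mean - od_control_mean)
}

#' Normalised heart-rate recovery rate of a fraction
#'
#' `R_i = 100 * (B_i - B_M) / (B_C - B_M)` where `B_i`, `B_M`, `B_C` are
#' the (group-mean) beat rates of the fraction-treated, model, and control
#' groups.  100% means full restoration of the control rate, 0% no effect;
#' values below 0 (fraction worsens the rate) or above 100 are permitted.
#'
#' @param b_i Treated-group beat rate(s), beats/min (vectorised).
#' @param b_m Model-group beat rate, beats/min.
#' @param b_c Control-group beat rate, beats/min; must differ from `b_m`.
#' @return Recovery rate(s) in percent.
#' @export
recovery_rate <- function(b_i, b_m, b_c) {
  if (b_c == b_m)
    stop("recovery rate undefined: model rate equals control rate")
  100 * (b_i - b_m) / (b_c - b_m)
}

#' Heart rate normalised to the control mean
#'
#' @param b_i Beat rate(s), beats/min.
#' @param b_c_mean Control-group mean rate, beats/min, > 0.
#' @return `b_i / b_c_mean` (unitless fraction).
#' @export
normalized_heart_rate <- function(b_i, b_c_mean) {
  if (!is.numeric(b_c_mean) || b_c_mean <= 0)
    stop("control mean rate must be positive")
  b_i / b_c_mean
}

#' Group summary: mean, sample SD, n
#'
#' @param values Numeric vector, non-empty.
#' @return List with `mean`, `sd` (n-1 denominator; 0 for a single value),
#'   and `n`.
#' @export
group_summary <- function(values) {
  if (!length(values) || !is.numeric(values))
    stop("values must be a non-empty numeric vector")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values))
}

#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way analysis of variance (equal-variance F
#' test), as used for between-group comparisons of plate and larva
#' readouts.
#'
#' @param groups Named list of numeric vectors, >= 2 groups each with >= 2
#'   values.
#' @return List with `f` and `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs at least two values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  tab <- summary(stats::aov(value ~ group, data = df))[[1]]
  list(f = tab[1, "F value"], p = tab[1, "Pr(>F)"])
}
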