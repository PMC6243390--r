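# Synthetic fraction-assay tables and MTT plates with planted ground truth.

#' Configuration for a synthetic fraction x compound assay
#'
#' Emulates the input of activity-index screening: a matrix of LC peak
#' areas of `n_compounds` constituents across `n_fractions` chromatographic
#' fractions, plus a per-fraction heart-rate recovery vector.  Inactive
#' compounds receive log-normal areas spread across all fractions; each
#' planted active has at least `active_share` of its total area
#' concentrated in its assigned high-recovery fraction(s).
#'
#' @param n_fractions Number of fractions (default 10).
#' @param n_compounds Number of compounds (default 71).
#' @param n_active Number of planted active compounds (default 1).
#' @param recovery_rates Per-fraction recovery rates R_i in percent
#'   (length `n_fractions`); may be negative.  The default profile mirrors a
#'   typical screen: early fractions beneficial, late ones harmful.
#' @param active_placement Optional named list mapping active compound ids
#'   to fraction indices; by default active k is assigned the fraction with
#'   the k-th highest recovery.
#' @param active_share Fraction of a planted active's total area placed in
#'   its assigned fractions (default 0.85, satisfying the >= 0.8 design).
#' @param area_lognorm_sigma Log-scale SD of peak areas (default 0.5).
#' @param area_lognorm_mu Log-scale mean of peak areas (default log(1e5)).
#' @param seed Optional RNG seed.
#' @return A list of class `"assay_sim_config"`.
#' @export
assay_sim_config <- function(n_fractions = 10, n_compounds = 71,
                             n_active = 1,
                             recovery_rates = c(60, 75, 40, 20, 10,
                                                0, -10, -20, 5, 15),
                             active_placement = NULL,
                             active_share = 0.85,
                             area_lognorm_sigma = 0.5,
                             area_lognorm_mu = log(1e5),
                             seed = NULL) {
  if (length(recovery_rates) != n_fractions)
    stop("recovery_rates must have length n_fractions")
  if (n_active > n_compounds) stop("n_active must be <= n_compounds")
  if (active_share < 0.8 || active_share > 1)
    stop("active_share must be in [0.8, 1]")
  structure(list(n_fractions = n_fractions, n_compounds = n_compounds,
                 n_active = n_active, recovery_rates = recovery_rates,
                 active_placement = active_placement,
                 active_share = active_share,
                 area_lognorm_sigma = area_lognorm_sigma,
                 area_lognorm_mu = area_lognorm_mu, seed = seed),
            class = "assay_sim_config")
}

#' Generate a synthetic fraction x compound peak-area matrix
#'
#' @param cfg An [assay_sim_config()].
#' @return List with `areas` (n_fractions x n_compounds matrix, fractions as
#'   rows), `recovery` (named per-fraction R_i, percent), and `actives`
#'   (ids of planted active compounds).
#' @export
generate_fraction_assay <- function(cfg = assay_sim_config()) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cfg$n_fractions; p <- cfg$n_compounds
  frac_ids <- sprintf("F%02d", seq_len(m))
  cmpd_ids <- sprintf("cmpd_%02d", seq_len(p))
  actives <- cmpd_ids[seq_len(cfg$n_active)]
  placement <- cfg$active_placement
  if (is.null(placement) && cfg$n_active > 0) {
    top <- order(cfg$recovery_rates, decreasing = TRUE)
    placement <- stats::setNames(as.list(top[seq_len(cfg$n_active)]), actives)
  }
  areas <- matrix(
    stats::rlnorm(m * p, meanlog = cfg$area_lognorm_mu,
                  sdlog = cfg$area_lognorm_sigma),
    nrow = m, dimnames = list(frac_ids, cmpd_ids))
  for (id in actives) {
    idx <- placement[[id]]
    x <- areas[, id]; tot <- sum(x)
    out <- setdiff(seq_len(m), idx)
    x[idx] <- cfg$active_share * tot * x[idx] / sum(x[idx])
    if (length(out))
      x[out] <- (1 - cfg$active_share) * tot * x[out] / sum(x[out])
    areas[, id] <- x
  }
  list(areas = areas,
       recovery = stats::setNames(cfg$recovery_rates, frac_ids),
       actives = actives)
}

#' Generate a synthetic MTT plate
#'
#' Gaussian optical-density (OD) replicates per group, truncated at zero.
#'
#' @param n_wells Replicates per group.
#' @param od_control_mean Mean OD of untreated cells.
#' @param od_model_mean Mean OD of oxidant-injured cells.
#' @param od_tested_mean Named numeric vector of mean ODs for treated
#'   groups (one entry per tested fraction), or a single unnamed value.
#' @param noise_sd SD of the OD noise.
#' @param seed Optional RNG seed.
#' @return Long data.frame with columns `group`, `well`, `od`.
#' @export
generate_mtt <- function(n_wells = 6, od_control_mean = 0.9,
                         od_model_mean = 0.45,
                         od_tested_mean = c(F01 = 0.75),
                         noise_sd = 0.05, seed = NULL) {
  if (od_control_mean <= 0 || od_model_mean <= 0 || any(od_tested_mean <= 0))
    stop("group mean ODs must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(od_tested_mean)))
    names(od_tested_mean) <- sprintf("F%02d", seq_along(od_tested_mean))
  draw <- function(mu) pmax(0, mu + stats::rnorm(n_wells, sd = noise_sd))
  groups <- c(control = od_control_mean, model = od_model_mean,
              od_tested_mean)
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, well = seq_len(n_wells), od = draw(groups[[g]]))
  }))
}
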