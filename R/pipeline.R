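# End-to-end demo screen on synthetic data: videos -> rates -> recovery ->
# peak-area matrix -> activity indexes -> dual scores, with a run manifest.

#' Configuration for the demo screen
#'
#' Each fraction carries an `effect` in model-to-control units: 1 restores
#' the control pacing rate, 0 leaves the model untouched, negative values
#' worsen it.  Treated-group video configs interpolate pacing, jitter, and
#' drop probability between the model and control presets by that effect.
#'
#' @param seed Master RNG seed; all per-larva seeds derive from it.
#' @param n_larvae Larvae per group (default 8).
#' @param fraction_effects Named numeric vector of per-fraction effects.
#' @param concentration_ug_ml Fraction dose recorded as metadata (default
#'   50).
#' @param terfenadine_um Model-inducer dose recorded as metadata (default 6).
#' @param n_compounds Compounds in the simulated peak-area matrix.
#' @param n_frames,fps Video geometry passed to the generators.
#' @param out_dir Output directory for the report bundle.
#' @return List of class `"screen_config"`.
#' @export
screen_config <- function(seed = 1, n_larvae = 8,
                          fraction_effects = c(F01 = 0.9, F02 = 0.75,
                                               F03 = 0.45, F04 = -0.15,
                                               F05 = 0.2),
                          concentration_ug_ml = 50, terfenadine_um = 6,
                          n_compounds = 71, n_frames = 100, fps = 20,
                          out_dir = tempfile("screen")) {
  if (n_larvae < 1) stop("n_larvae must be >= 1")
  if (is.null(names(fraction_effects)))
    names(fraction_effects) <- sprintf("F%02d", seq_along(fraction_effects))
  structure(list(seed = seed, n_larvae = n_larvae,
                 fraction_effects = fraction_effects,
                 concentration_ug_ml = concentration_ug_ml,
                 terfenadine_um = terfenadine_um,
                 n_compounds = n_compounds, n_frames = n_frames, fps = fps,
                 out_dir = out_dir),
            class = "screen_config")
}

# Interpolate a treated-group video config between model and control.
.treated_config <- function(effect, n_frames, fps, seed) {
  ctrl <- video_preset("control-larva")
  mod <- video_preset("model-larva")
  e <- min(max(effect, -1), 1)
  mix <- function(a, b) b + e * (a - b)
  video_config(n_frames = n_frames, fps = fps,
               beat_hz = mix(ctrl$beat_hz, mod$beat_hz),
               ibi_jitter_cv = max(0, mix(ctrl$ibi_jitter_cv,
                                          mod$ibi_jitter_cv)),
               dropped_beat_prob = max(0, mix(ctrl$dropped_beat_prob,
                                              mod$dropped_beat_prob)),
               seed = seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full demo screen on synthetic data
#'
#' Generates per-group heart videos, measures beat rates through the
#' imaging pipeline, computes per-fraction recovery rates, simulates the
#' fraction x compound peak-area matrix with one planted active in the
#' top-recovery fraction, computes activity indexes, the bio-active map,
#' MTT-based protection coefficients and dual scores, and writes every
#' table plus a JSON manifest to `cfg$out_dir`.  Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param cfg A [screen_config()].
#' @return Invisibly, a list with the output `paths`, the per-larva `rates`
#'   table, `recovery`, ranked `scores`, `dual`, and `actives`.
#' @export
run_demo_screen <- function(cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fractions <- names(cfg$fraction_effects)
  groups <- c("control", "model", fractions)

  configs <- .stage("configure", {
    cfgs <- list(
      control = video_preset("control-larva", n_frames = cfg$n_frames,
                             fps = cfg$fps),
      model = video_preset("model-larva", n_frames = cfg$n_frames,
                           fps = cfg$fps)
    )
    for (f in fractions)
      cfgs[[f]] <- .treated_config(cfg$fraction_effects[[f]],
                                   cfg$n_frames, cfg$fps, seed = NULL)
    cfgs
  })

  rates <- .stage("imaging", {
    do.call(rbind, lapply(seq_along(groups), function(gi) {
      g <- groups[gi]
      do.call(rbind, lapply(seq_len(cfg$n_larvae), function(li) {
        vc <- configs[[g]]
        vc$seed <- cfg$seed * 100000 + gi * 1000 + li
        video <- generate_heart_video(vc)
        beats <- analyze_stack(video$stack)
        data.frame(group = g, larva = li, bpm = beats$bpm,
                   n_peaks = beats$n_peaks,
                   ibi_cv = ifelse(is.na(beats$ibi_cv), NA, beats$ibi_cv),
                   dropped_beats = beats$dropped_beats,
                   irregular = beats$irregular,
                   concentration_ug_ml = ifelse(
                     g %in% fractions, cfg$concentration_ug_ml, NA),
                   stringsAsFactors = FALSE)
      }))
    }))
  })

  recovery <- .stage("recovery", {
    gmean <- tapply(rates$bpm, rates$group, mean)
    stats::setNames(
      recovery_rate(as.numeric(gmean[fractions]),
                    gmean[["model"]], gmean[["control"]]),
      fractions)
  })

  assay <- .stage("assay", {
    generate_fraction_assay(assay_sim_config(
      n_fractions = length(fractions), n_compounds = cfg$n_compounds,
      n_active = 1, recovery_rates = as.numeric(recovery),
      seed = cfg$seed + 7919))
  })

  scores <- .stage("scoring", {
    norm <- normalize_areas(assay$areas)
    rank_compounds(activity_indexes(norm, recovery))
  })
  bmap <- bioactive_map(normalize_areas(assay$areas), recovery)

  dual <- .stage("mtt", {
    # treated OD interpolates injury -> control by the same fraction effect
    od_c <- 0.9; od_m <- 0.45
    od_t <- stats::setNames(
      od_m + pmin(pmax(cfg$fraction_effects, -1), 1) * (od_c - od_m),
      fractions)
    plate <- generate_mtt(n_wells = 6, od_control_mean = od_c,
                          od_model_mean = od_m, od_tested_mean = od_t,
                          noise_sd = 0.03, seed = cfg$seed + 104729)
    gm <- tapply(plate$od, plate$group, mean)
    prot <- stats::setNames(
      protection_rate(as.numeric(gm[fractions]), gm[["model"]],
                      gm[["control"]]), fractions)
    cell_scores <- activity_indexes(normalize_areas(assay$areas), prot)
    utils::write.csv(plate, file.path(cfg$out_dir, "mtt_plate.csv"),
                     row.names = FALSE)
    dual_scores(activity_indexes(normalize_areas(assay$areas), recovery),
                cell_scores)
  })

  paths <- .stage("report", {
    p <- list(
      rates = file.path(cfg$out_dir, "larva_rates.csv"),
      recovery = file.path(cfg$out_dir, "fraction_recovery.csv"),
      areas = file.path(cfg$out_dir, "peak_areas.csv"),
      scores = file.path(cfg$out_dir, "activity_index.csv"),
      bioactive_map = file.path(cfg$out_dir, "bioactive_map.csv"),
      dual = file.path(cfg$out_dir, "dual_scores.csv"),
      manifest = file.path(cfg$out_dir, "manifest.json")
    )
    utils::write.csv(rates, p$rates, row.names = FALSE)
    utils::write.csv(data.frame(fraction = names(recovery),
                                recovery_pct = as.numeric(recovery)),
                     p$recovery, row.names = FALSE)
    utils::write.csv(as.data.frame(assay$areas), p$areas)
    utils::write.csv(as.data.frame(scores), p$scores, row.names = FALSE)
    utils::write.csv(as.data.frame(bmap), p$bioactive_map)
    utils::write.csv(dual, p$dual, row.names = FALSE)
    csvs <- unlist(p[names(p) != "manifest"])
    manifest <- list(
      package = "cardioscreen",
      version = as.character(utils::packageVersion("cardioscreen")),
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "out_dir")],
      stages = c("configure", "imaging", "recovery", "assay", "scoring",
                 "mtt", "report"),
      planted_actives = assay$actives,
      files = as.list(tools::md5sum(csvs))
    )
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE,
                         digits = NA)
    p
  })

  invisible(list(paths = paths, rates = rates, recovery = recovery,
                 scores = scores, dual = dual, actives = assay$actives))
}
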