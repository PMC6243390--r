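# Synthetic fluorescence heart videos and ECG traces with known ground truth.
#
# A beating larval heart imaged in a Cmlc2-GFP line appears as a single
# bright region on a dark background whose projected area oscillates with
# the cardiac cycle.  The generator draws per-cycle periods (optionally
# jittered), holds the diastolic (maximal-area) state through "dropped"
# cycles to emulate atrioventricular block, and rasterises a filled ellipse
# whose area follows baseline * (1 + pulsation_fraction * cos(phase)).

#' Configuration for a synthetic heart video
#'
#' @param n_frames Number of frames (default 100, one acquisition burst).
#' @param fps Frames per second, 10 or 20 (default 20).
#' @param beat_hz Underlying pacing rate in Hz.
#' @param area_baseline Mean projected heart area in pixels.
#' @param pulsation_fraction Fractional area modulation over a cycle (0-1).
#' @param frame_shape `c(rows, cols)` of each frame (8-bit grayscale).
#' @param noise_sd Additive Gaussian intensity noise (0-255 scale).
#' @param dropped_beat_prob Per-cycle probability of a skipped ventricular
#'   contraction (held diastole), in `[0, 1)`.
#' @param ibi_jitter_cv Coefficient of variation of the per-cycle period.
#' @param axis_ratio Major/minor axis ratio of the heart ellipse.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class `"video_config"`.
#' @export
video_config <- function(n_frames = 100, fps = 20, beat_hz = 3,
                         area_baseline = 1200, pulsation_fraction = 0.3,
                         frame_shape = c(128, 128), noise_sd = 3,
                         dropped_beat_prob = 0, ibi_jitter_cv = 0,
                         axis_ratio = 1.5, seed = NULL) {
  cfg <- list(n_frames = n_frames, fps = fps, beat_hz = beat_hz,
              area_baseline = area_baseline,
              pulsation_fraction = pulsation_fraction,
              frame_shape = frame_shape, noise_sd = noise_sd,
              dropped_beat_prob = dropped_beat_prob,
              ibi_jitter_cv = ibi_jitter_cv, axis_ratio = axis_ratio,
              seed = seed)
  duration <- n_frames / fps
  if (!fps %in% c(10, 20)) stop("fps must be 10 or 20")
  if (duration <= 2 / beat_hz)
    stop("recording must span at least two full cycles")
  if (beat_hz >= fps / 2)
    stop("beat_hz must be below the Nyquist rate fps/2")
  if (dropped_beat_prob < 0 || dropped_beat_prob >= 1)
    stop("dropped_beat_prob must be in [0, 1)")
  if (pulsation_fraction < 0 || pulsation_fraction > 1)
    stop("pulsation_fraction must be in [0, 1]")
  class(cfg) <- "video_config"
  cfg
}

#' Named video presets encoding the study conditions
#'
#' `"control-larva"`: regular ~3 Hz beat (180 beats/min).
#' `"model-larva"`: terfenadine-type bradycardia at 1.5 Hz pacing
#' (90 beats/min, the middle of the 80-100 beats/min band typical of the
#' model condition) with irregular intervals and occasional dropped
#' (blocked) ventricular contractions.
#'
#' @param preset Preset name.
#' @param seed Optional RNG seed stored in the returned config.
#' @param ... Overrides passed on to [video_config()].
#' @return A `"video_config"`.
#' @export
video_preset <- function(preset = c("control-larva", "model-larva"),
                         seed = NULL, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "control-larva" = list(beat_hz = 3, ibi_jitter_cv = 0.02,
                           dropped_beat_prob = 0),
    "model-larva"   = list(beat_hz = 1.5, ibi_jitter_cv = 0.3,
                           dropped_beat_prob = 0.05)
  )
  do.call(video_config, utils::modifyList(c(args, list(seed = seed)),
                                          list(...)))
}

# Draw cycle start times / periods / dropped flags covering [0, duration].
# The recording starts half-way through the first cycle (acquisition begins
# at an arbitrary cardiac phase), so diastolic maxima fall in the interior
# of the trace rather than on its first sample.
.draw_cycles <- function(duration, beat_hz, jitter_cv, drop_prob) {
  t0 <- 1 / beat_hz
  starts <- numeric(0); periods <- numeric(0); dropped <- logical(0)
  p1 <- if (jitter_cv > 0) t0 * max(0.2, 1 + jitter_cv * stats::rnorm(1)) else t0
  t <- -p1 / 2
  first <- TRUE
  while (t < duration) {
    p <- if (first) p1 else if (jitter_cv > 0)
      t0 * max(0.2, 1 + jitter_cv * stats::rnorm(1)) else t0
    first <- FALSE
    starts <- c(starts, t); periods <- c(periods, p)
    dropped <- c(dropped, drop_prob > 0 && stats::runif(1) < drop_prob)
    t <- t + p
  }
  list(starts = starts, periods = periods, dropped = dropped)
}

# Analytic heart area at arbitrary times given a cycle layout.
.area_at <- function(times, cycles, baseline, pf) {
  idx <- findInterval(times, cycles$starts)
  idx[idx < 1L] <- 1L
  phase <- 2 * pi * (times - cycles$starts[idx]) / cycles$periods[idx]
  a <- baseline * (1 + pf * cos(phase))
  a[cycles$dropped[idx]] <- baseline * (1 + pf)  # held diastole
  a
}

#' Generate a synthetic fluorescence heart video
#'
#' @param cfg A [video_config()] (or preset from [video_preset()]).
#' @return List with `stack` (an [image_stack()]) and `truth`: `true_bpm`
#'   (60 x pacing rate), `true_beat_times` (starts of non-dropped cycles, s),
#'   `dropped_cycles` (indices), `true_area_series` (analytic area per
#'   frame, px), and the generating `config`.
#' @export
generate_heart_video <- function(cfg = video_config()) {
  stopifnot(inherits(cfg, "video_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  duration <- cfg$n_frames / cfg$fps
  cycles <- .draw_cycles(duration, cfg$beat_hz, cfg$ibi_jitter_cv,
                         cfg$dropped_beat_prob)
  times <- (seq_len(cfg$n_frames) - 1L) / cfg$fps
  areas <- .area_at(times, cycles, cfg$area_baseline, cfg$pulsation_fraction)

  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  row_d <- matrix(seq_len(nr) - cy, nr, nc)
  col_d <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  bg <- 20; fg <- 200
  frames <- array(0, dim = c(nr, nc, cfg$n_frames))
  for (k in seq_len(cfg$n_frames)) {
    b <- sqrt(areas[k] / (pi * cfg$axis_ratio))   # minor semi-axis
    a <- cfg$axis_ratio * b                       # major semi-axis
    inside <- (col_d / a)^2 + (row_d / b)^2 <= 1
    img <- bg + (fg - bg) * inside
    if (cfg$noise_sd > 0)
      img <- img + stats::rnorm(nr * nc, sd = cfg$noise_sd)
    frames[, , k] <- round(pmin(pmax(img, 0), 255))
  }
  in_range <- cycles$starts >= 0 & cycles$starts < duration
  list(
    stack = image_stack(frames, cfg$fps),
    truth = list(
      true_bpm = 60 * cfg$beat_hz,
      true_beat_times = cycles$starts[in_range & !cycles$dropped],
      dropped_cycles = which(cycles$dropped & in_range),
      true_area_series = areas,
      config = cfg
    )
  )
}

#' Write / read an image stack as multi-page 8-bit TIFF
#'
#' `write_stack()` also writes a JSON sidecar (`<path>.json`) carrying the
#' frame rate and, if supplied, the generator ground truth.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param truth Optional ground-truth list to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(k) stack$frames[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- list(fps = stack$fps)
  if (!is.null(truth))
    sidecar$truth <- truth[c("true_bpm", "true_beat_times", "dropped_cycles")]
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @param fps Frame rate; if `NULL`, read from the JSON sidecar.
#' @export
read_stack <- function(path, fps = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(fps)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("fps not given and no sidecar found at ", sidecar)
    fps <- jsonlite::read_json(sidecar)$fps
  }
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # grayscale written as-is
    frames[, , k] <- round(pg * 255)
  }
  image_stack(frames, fps)
}

#' Configuration for a synthetic zebrafish ECG trace
#'
#' @param duration Recording length, s.
#' @param sample_rate Sampling rate, Hz (must be >= 50 x `beat_hz`).
#' @param beat_hz Heart rate in Hz.
#' @param qrs_amplitude Peak amplitude of the QRS-like template (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.).
#' @param ibi_jitter_cv Coefficient of variation of beat intervals.
#' @param seed Optional RNG seed.
#' @return A list of class `"ecg_config"`.
#' @export
ecg_config <- function(duration = 10, sample_rate = 1000, beat_hz = 100 / 60,
                       qrs_amplitude = 1, noise_sd = 0.05,
                       ibi_jitter_cv = 0, seed = NULL) {
  if (sample_rate < 50 * beat_hz)
    stop("sample_rate must be at least 50 x beat_hz")
  if (duration <= 2 / beat_hz) stop("duration must span at least two beats")
  structure(list(duration = duration, sample_rate = sample_rate,
                 beat_hz = beat_hz, qrs_amplitude = qrs_amplitude,
                 noise_sd = noise_sd, ibi_jitter_cv = ibi_jitter_cv,
                 seed = seed),
            class = "ecg_config")
}

#' ECG presets for adult zebrafish
#'
#' `"adult-normal"`: regular ~100 beats/min.  `"adult-terfenadine"`:
#' slowed, irregular rhythm after terfenadine exposure.
#'
#' @inheritParams video_preset
#' @return An `"ecg_config"`.
#' @export
ecg_preset <- function(preset = c("adult-normal", "adult-terfenadine"),
                       seed = NULL, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "adult-normal"      = list(beat_hz = 100 / 60, ibi_jitter_cv = 0.03),
    "adult-terfenadine" = list(beat_hz = 1.2, ibi_jitter_cv = 0.25)
  )
  do.call(ecg_config, utils::modifyList(c(args, list(seed = seed)),
                                        list(...)))
}

#' Generate a synthetic ECG trace
#'
#' Baseline plus a biphasic QRS-like template at (optionally jittered) beat
#' times plus Gaussian noise.
#'
#' @param cfg An [ecg_config()].
#' @return List with `trace` (data.frame `time_s`, `voltage`) and `truth`
#'   (`true_bpm`, `beat_times`, `config`).
#' @export
generate_ecg <- function(cfg = ecg_config()) {
  stopifnot(inherits(cfg, "ecg_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t0 <- 1 / cfg$beat_hz
  beats <- numeric(0); t <- t0 / 2  # first beat mid-way into the record
  while (t < cfg$duration) {
    beats <- c(beats, t)
    step <- if (cfg$ibi_jitter_cv > 0)
      t0 * max(0.2, 1 + cfg$ibi_jitter_cv * stats::rnorm(1)) else t0
    t <- t + step
  }
  times <- seq(0, cfg$duration, by = 1 / cfg$sample_rate)
  v <- numeric(length(times))
  for (b in beats) {
    # biphasic template: sharp R upstroke followed by a shallower S dip
    dt <- times - b
    win <- abs(dt) < 0.12
    v[win] <- v[win] + cfg$qrs_amplitude *
      (exp(-0.5 * (dt[win] / 0.012)^2) -
       0.45 * exp(-0.5 * ((dt[win] - 0.03) / 0.015)^2))
  }
  if (cfg$noise_sd > 0) v <- v + stats::rnorm(length(v), sd = cfg$noise_sd)
  list(
    trace = data.frame(time_s = times, voltage = v),
    truth = list(true_bpm = 60 * cfg$beat_hz, beat_times = beats,
                 config = cfg)
  )
}

#' Write / read an ECG trace as a two-column CSV
#'
#' @param trace Data.frame with `time_s` and `voltage`.
#' @param path CSV path.
#' @return `path` (write) or the trace data.frame (read).
#' @export
write_ecg <- function(trace, path) {
  stopifnot(all(c("time_s", "voltage") %in% names(trace)))
  utils::write.csv(trace[c("time_s", "voltage")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg
#' @export
read_ecg <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage") %in% names(df)))
    stop("ECG CSV must have columns time_s and voltage")
  df
}
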