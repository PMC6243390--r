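# Heartbeat quantification from fluorescence frame stacks.
#
# The pipeline follows the bright-heart-on-dark-background geometry of a
# Cmlc2-GFP larva: threshold each frame (Otsu by default), keep the largest
# 8-connected component as the ventricle, count its pixels to form an
# area-versus-time trace, and read rate and rhythm off the trace peaks.

#' Construct an image stack
#'
#' @param frames Numeric array `(rows, cols, n_frames)` of intensities.
#' @param fps Frame rate, frames/s.
#' @return List of class `"image_stack"` with `frames` and `fps`.
#' @export
image_stack <- function(frames, fps) {
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    stop("frames must be a (rows, cols, n_frames) array with >= 2 frames")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  structure(list(frames = frames, fps = fps), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %dx%d px at %g fps (%.2f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

# Merge 4-connected labels that touch diagonally so components are
# 8-connected (EBImage::bwlabel is 4-connected).
.merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, 0L)
  out <- lab
  out[lab > 0] <- root[lab[lab > 0]]
  out
}

#' Segment the heart in a single frame
#'
#' Thresholds the frame (Otsu's criterion on the intensity-normalised image
#' by default, or a supplied fixed value) and keeps only the largest
#' 8-connected foreground component.  An empty mask is a valid result.
#'
#' @param frame Numeric intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold on the raw intensity scale, required
#'   when `method = "fixed"`.
#' @return Logical matrix of the same shape.
#' @export
segment_heart <- function(frame, method = c("otsu", "fixed"),
                          fixed_threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a matrix")
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop("fixed method requires fixed_threshold")
    mask <- frame > fixed_threshold
  } else {
    rng <- range(frame)
    if (diff(rng) == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
    x01 <- (frame - rng[1]) / diff(rng)
    th <- EBImage::otsu(x01, range = c(0, 1))
    mask <- x01 > th
  }
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(frame), ncol(frame))
  if (max(lab) > 1L) lab <- .merge_diagonal(lab)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Heart-area time series of a stack
#'
#' Applies [segment_heart()] to every frame and counts mask pixels.
#'
#' @param stack An [image_stack()].
#' @param method,fixed_threshold Passed to [segment_heart()].
#' @return Data.frame of class `"area_trace"` with `time_s` (frame index /
#'   fps) and `area_px`, plus attribute `fps`.
#' @export
area_trace <- function(stack, method = "otsu", fixed_threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3]
  areas <- vapply(seq_len(n), function(k) {
    sum(segment_heart(stack$frames[, , k], method, fixed_threshold))
  }, 0)
  out <- data.frame(time_s = (seq_len(n) - 1L) / stack$fps, area_px = areas)
  attr(out, "fps") <- stack$fps
  class(out) <- c("area_trace", "data.frame")
  out
}

# Moving average with edges filled from the input signal.
.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

# Local maxima (leftmost point of plateaus), their prominences, and
# greedy minimum-separation enforcement (highest peaks win).  Candidates
# separated only by a dip shallower than plateau_tol belong to one (noisy)
# plateau and collapse to a single peak -- the higher one, leftmost on ties.
.find_peaks <- function(x, min_prominence, min_sep_samples,
                        plateau_tol = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  if (plateau_tol > 0 && length(cand) > 1L) {
    kept <- cand[1L]
    for (c in cand[-1L]) {
      k <- kept[length(kept)]
      dip <- min(x[k:c])
      if (dip >= min(x[k], x[c]) - plateau_tol) {
        if (x[c] > x[k]) kept[length(kept)] <- c  # same plateau
      } else kept <- c(kept, c)
    }
    cand <- kept
  }
  prom <- vapply(cand, function(p) {
    lmin <- x[p]
    for (j in seq(p - 1L, 1L)) {
      if (x[j] > x[p]) break
      lmin <- min(lmin, x[j])
    }
    rmin <- x[p]
    for (j in seq(p + 1L, n)) {
      if (x[j] > x[p]) break
      rmin <- min(rmin, x[j])
    }
    x[p] - max(lmin, rmin)
  }, 0)
  cand <- cand[prom >= min_prominence]
  if (length(cand) <= 1L) return(cand)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_sep_samples))
      kept <- c(kept, p)
  sort(kept)
}

# Shared beat-detection core on a uniformly sampled signal.
.detect_beats_core <- function(times, values, rate, min_prominence_frac,
                               min_separation_s, smooth_window_s,
                               detrend_window_s = Inf,
                               irregular_cv_threshold = 0.15,
                               dropped_ibi_factor = 1.75,
                               amp_quantiles = c(0.05, 0.95)) {
  n <- length(values)
  k <- min(n, round(detrend_window_s * rate))
  if (k %% 2 == 0) k <- k - 1L
  # window >= recording length degenerates to a global median subtract;
  # a finite window only helps on long recordings with baseline drift and
  # must stay well above one cardiac cycle or blocked-beat plateaus are
  # flattened into the median
  detrended <- if (!is.finite(detrend_window_s) || k >= n - 1L || k < 3)
    values - stats::median(values) else values - stats::runmed(values, k)
  w <- round(smooth_window_s * rate)
  if (w %% 2 == 0) w <- w + 1L
  sm <- .moving_average(detrended, w)
  amp <- diff(stats::quantile(sm, amp_quantiles, names = FALSE))
  # quantise to 2% of the signal amplitude so that noise riding on a held
  # (blocked-beat) plateau collapses to exact ties, which the leftmost-
  # sample plateau rule then resolves deterministically
  q <- 0
  if (amp > 0) {
    q <- amp / 50
    sm <- round(sm / q) * q
  }
  peaks <- if (amp > 0)
    .find_peaks(sm, min_prominence_frac * amp,
                min_separation_s * rate, plateau_tol = 2 * q) else integer(0)
  res <- list(peak_times = times[peaks], peak_indices = peaks,
              n_peaks = length(peaks))
  res$no_rhythm <- res$n_peaks < 2L
  res$bpm <- if (res$no_rhythm) 0 else heart_rate(res$peak_times)
  metrics <- rhythm_metrics(res$peak_times,
                            irregular_cv_threshold = irregular_cv_threshold,
                            dropped_ibi_factor = dropped_ibi_factor)
  res[names(metrics)] <- metrics
  class(res) <- "beat_analysis"
  res
}

#' @export
print.beat_analysis <- function(x, ...) {
  cat(sprintf(
    "beat_analysis: %d peaks, %.1f beats/min%s, ibi_cv %s, dropped %s%s\n",
    x$n_peaks, x$bpm, if (x$no_rhythm) " (no rhythm)" else "",
    ifelse(is.na(x$ibi_cv), "NA", sprintf("%.3f", x$ibi_cv)),
    ifelse(is.na(x$dropped_beats), "NA", x$dropped_beats),
    if (isTRUE(x$irregular)) ", irregular" else ""))
  invisible(x)
}

#' Detect beats in a heart-area trace
#'
#' Detrends the area series by subtracting a running median (by default the
#' window spans the whole recording, i.e. a global median: recordings here
#' are a few seconds and drift-free, and short windows flatten the held
#' diastolic plateau of a blocked beat into the median; set a finite
#' `detrend_window_s` of several cycles for long drifting recordings),
#' smooths
#' with a short moving average, and finds local maxima with prominence at
#' least `min_prominence_frac` of the 5th-95th percentile span of the
#' detrended signal, separated by at least `min_separation_s`.  Fewer than
#' two peaks yields `bpm = 0` and the `no_rhythm` flag rather than an error
#' so batch runs never abort.
#'
#' @param trace An [area_trace()] (or data.frame with `time_s` and
#'   `area_px` plus an `fps` attribute).
#' @param min_prominence_frac Prominence floor as a fraction of signal
#'   amplitude (default 0.3).
#' @param min_separation_s Minimum peak separation, s (default 0.15, i.e. a
#'   400 beats/min ceiling, safely above larval physiology).
#' @param smooth_window_s Moving-average window, s (default 0.1).
#' @param detrend_window_s Running-median detrend window, s (default `Inf`:
#'   global median).
#' @return A `"beat_analysis"` list: `peak_times`, `n_peaks`, `bpm`,
#'   `ibis`, `ibi_cv`, `dropped_beats`, `irregular`, `no_rhythm`.
#' @export
detect_beats <- function(trace, min_prominence_frac = 0.3,
                         min_separation_s = 0.15, smooth_window_s = 0.1,
                         detrend_window_s = Inf) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "area_px") %in% names(trace)))
  if (nrow(trace) < 4L) stop("trace must have at least 4 samples")
  fps <- attr(trace, "fps")
  if (is.null(fps)) fps <- 1 / stats::median(diff(trace$time_s))
  .detect_beats_core(trace$time_s, trace$area_px, fps,
                     min_prominence_frac, min_separation_s, smooth_window_s,
                     detrend_window_s)
}

#' Detect beats (R peaks) in an ECG trace
#'
#' Same detection contract as [detect_beats()] applied to the voltage
#' series, with two adjustments for spike-train morphology: the smoothing
#' window is shorter so the narrow QRS complex is not blurred away, and the
#' amplitude reference for the prominence floor is the signal maximum
#' rather than the 95th percentile (QRS complexes occupy a few percent of
#' samples, so upper percentiles sit in the noise floor at low rates).
#'
#' @param trace Data.frame with `time_s` and `voltage`.
#' @inheritParams detect_beats
#' @return A `"beat_analysis"`.
#' @export
detect_beats_ecg <- function(trace, min_prominence_frac = 0.3,
                             min_separation_s = 0.15,
                             smooth_window_s = 0.01,
                             detrend_window_s = Inf) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "voltage") %in% names(trace)))
  span <- diff(range(trace$time_s))
  if (span < 1) stop("need at least 1 s of ECG signal")
  rate <- 1 / stats::median(diff(trace$time_s))
  .detect_beats_core(trace$time_s, trace$voltage, rate,
                     min_prominence_frac, min_separation_s, smooth_window_s,
                     detrend_window_s, amp_quantiles = c(0.05, 1))
}

#' Heart rate from detected beats
#'
#' `60 * (n_peaks - 1) / (last peak time - first peak time)`; unbiased for
#' partial cycles at the ends of short recordings.  Fewer than two peaks
#' gives 0.
#'
#' @param beats A `"beat_analysis"` or a numeric vector of peak times (s).
#' @return Rate in beats/min.
#' @export
heart_rate <- function(beats) {
  pt <- if (inherits(beats, "beat_analysis")) beats$peak_times else beats
  if (length(pt) < 2L) return(0)
  60 * (length(pt) - 1L) / (pt[length(pt)] - pt[1L])
}

#' Rhythm regularity metrics from detected beats
#'
#' Inter-beat intervals (IBIs) are successive peak-time differences.
#' `ibi_cv = sd(ibis) / mean(ibis)` (needs >= 3 peaks, otherwise `NA`);
#' the rhythm is flagged irregular when `ibi_cv` exceeds
#' `irregular_cv_threshold`; an IBI longer than `dropped_ibi_factor` times
#' the median IBI counts as a dropped (blocked) beat.
#'
#' @param beats A `"beat_analysis"` or numeric peak times (s).
#' @param irregular_cv_threshold CV above which the rhythm is irregular
#'   (default 0.15).
#' @param dropped_ibi_factor Multiple of the median IBI flagging a dropped
#'   beat (default 1.75).
#' @return List with `ibis`, `ibi_cv`, `irregular`, `dropped_beats`.
#' @export
rhythm_metrics <- function(beats, irregular_cv_threshold = 0.15,
                           dropped_ibi_factor = 1.75) {
  pt <- if (inherits(beats, "beat_analysis")) beats$peak_times else beats
  ibis <- diff(pt)
  if (length(pt) < 3L)
    return(list(ibis = ibis, ibi_cv = NA_real_, irregular = NA,
                dropped_beats = NA_integer_))
  cv <- stats::sd(ibis) / mean(ibis)
  list(ibis = ibis, ibi_cv = cv,
       irregular = cv > irregular_cv_threshold,
       dropped_beats = sum(ibis > dropped_ibi_factor * stats::median(ibis)))
}

#' Full video-to-rate pipeline for one stack
#'
#' Convenience wrapper: [area_trace()] then [detect_beats()].
#'
#' @param stack An [image_stack()].
#' @param ... Passed to [detect_beats()].
#' @return A `"beat_analysis"`.
#' @export
analyze_stack <- function(stack, ...) {
  detect_beats(area_trace(stack), ...)
}
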