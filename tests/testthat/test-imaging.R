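make_blob_frame <- function(nr = 64, nc = 64, blobs) {
  f <- matrix(10, nr, nc)
  for (b in blobs) {
    rows <- b$row + seq(-b$r, b$r)
    cols <- b$col + seq(-b$r, b$r)
    grid <- expand.grid(r = rows, c = cols)
    keep <- (grid$r - b$row)^2 + (grid$c - b$col)^2 <= b$r^2
    f[as.matrix(grid[keep, ])] <- 200
  }
  f
}

test_that("segmentation recovers the generated ellipse area", {
  cfg <- video_config(noise_sd = 0, ibi_jitter_cv = 0, seed = 1)
  v <- generate_heart_video(cfg)
  mask <- segment_heart(v$stack$frames[, , 1])
  expect_lt(abs(sum(mask) / v$truth$true_area_series[1] - 1), 0.05)
})

test_that("segmentation keeps only the largest component", {
  two <- make_blob_frame(blobs = list(list(row = 16, col = 16, r = 3),
                                      list(row = 45, col = 45, r = 8)))
  mask <- segment_heart(two)
  expect_true(mask[45, 45])
  expect_false(mask[16, 16])
  # isolated single-pixel noise does not change the segmented area
  noisy <- two
  noisy[2, 2] <- 255
  noisy[60, 5] <- 255
  expect_equal(sum(segment_heart(noisy)), sum(mask))
})

test_that("segmentation handles degenerate frames and fixed thresholds", {
  expect_equal(sum(segment_heart(matrix(0, 8, 8))), 0)
  f <- make_blob_frame(blobs = list(list(row = 30, col = 30, r = 6)))
  expect_equal(sum(segment_heart(f, method = "fixed",
                                 fixed_threshold = 100)),
               sum(segment_heart(f)))
  expect_error(segment_heart(f, method = "fixed"), "fixed_threshold")
})

test_that("diagonally touching pixels join one 8-connected component", {
  f <- matrix(0, 16, 16)
  # staircase of diagonal pixels plus a smaller separate blob
  for (k in 0:4) f[4 + k, 4 + k] <- 200
  f[12, 4] <- 200
  mask <- segment_heart(f, method = "fixed", fixed_threshold = 100)
  expect_equal(sum(mask), 5)  # the staircase wins as one component
})

test_that("area trace has frame-locked times and tracks the truth", {
  v <- generate_heart_video(video_preset("control-larva", seed = 42))
  tr <- area_trace(v$stack)
  expect_equal(nrow(tr), 100)
  expect_equal(tr$time_s[1], 0)
  expect_equal(tr$time_s[100], 4.95)
  expect_gt(stats::cor(tr$area_px, v$truth$true_area_series), 0.9)
})

test_that("beat detection finds one peak per cycle on the control preset", {
  v <- generate_heart_video(video_config(beat_hz = 3, ibi_jitter_cv = 0,
                                         noise_sd = 0, seed = 1))
  b <- analyze_stack(v$stack)
  expect_equal(b$n_peaks, 15)
  expect_equal(b$bpm, 180, tolerance = 0.05)
  expect_false(b$no_rhythm)
  expect_false(b$irregular)
})

test_that("a flat trace yields the no-rhythm flag, not an error", {
  flat <- data.frame(time_s = (0:99) / 20, area_px = rep(500, 100))
  attr(flat, "fps") <- 20
  b <- detect_beats(flat)
  expect_equal(b$n_peaks, 0)
  expect_true(b$no_rhythm)
  expect_equal(b$bpm, 0)
})

test_that("blocked cycles appear as dropped beats", {
  # one isolated interior held-diastole cycle in a 5 s record
  v <- generate_heart_video(video_config(beat_hz = 1.5, ibi_jitter_cv = 0,
                                         dropped_beat_prob = 0.25,
                                         seed = 1))
  expect_length(v$truth$dropped_cycles, 1)
  expect_equal(analyze_stack(v$stack)$dropped_beats, 1)
  # two isolated interior blocks in a 10 s record
  v2 <- generate_heart_video(video_config(n_frames = 200, beat_hz = 1.5,
                                          ibi_jitter_cv = 0,
                                          dropped_beat_prob = 0.12,
                                          seed = 5))
  expect_length(v2$truth$dropped_cycles, 2)
  expect_equal(analyze_stack(v2$stack)$dropped_beats, 2)
})

test_that("heart rate is exact arithmetic on peak times", {
  expect_equal(heart_rate(c(0, 1, 2, 3) / 3), 180)
  expect_equal(heart_rate(c(0, 0.6)), 100)
  expect_equal(heart_rate(0.5), 0)
  set.seed(33)
  for (i in 1:10) {
    delta <- stats::runif(1, 0.2, 1.5)
    peaks <- seq(0, by = delta, length.out = sample(3:20, 1))
    expect_equal(heart_rate(peaks), 60 / delta)
  }
})

test_that("rhythm metrics flag irregularity and long intervals", {
  even <- seq(0, 3, by = 0.3)
  m <- rhythm_metrics(even)
  expect_equal(m$ibi_cv, 0)
  expect_false(m$irregular)
  expect_equal(m$dropped_beats, 0)
  # one doubled interval among ten
  pt <- cumsum(c(0, rep(0.5, 9), 1.0))
  expect_equal(rhythm_metrics(pt)$dropped_beats, 1)
  expect_true(is.na(rhythm_metrics(c(0, 1))$ibi_cv))
})

test_that("detected rate is invariant to uniform intensity scaling", {
  v <- generate_heart_video(video_preset("control-larva", seed = 13))
  b1 <- analyze_stack(v$stack)
  scaled <- image_stack(v$stack$frames * 0.4, v$stack$fps)
  b2 <- analyze_stack(scaled)
  expect_equal(b2$bpm, b1$bpm)
  expect_equal(b2$peak_times, b1$peak_times)
})

test_that("ECG beat detection mirrors the area-trace contract", {
  zero <- data.frame(time_s = (0:2000) / 1000, voltage = rep(0, 2001))
  b <- detect_beats_ecg(zero)
  expect_true(b$no_rhythm)
  e <- generate_ecg(ecg_preset("adult-terfenadine", seed = 3))
  bt <- detect_beats_ecg(e$trace)
  expect_lt(bt$bpm, 90)
  expect_error(detect_beats_ecg(data.frame(time_s = c(0, 0.1),
                                           voltage = c(0, 1))), "1 s")
})
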