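test_that("video config enforces its physical invariants", {
  expect_error(video_config(fps = 30), "10 or 20")
  expect_error(video_config(beat_hz = 12, fps = 20), "Nyquist")
  expect_error(video_config(n_frames = 10, fps = 20, beat_hz = 1),
               "two full cycles")
  expect_error(video_config(dropped_beat_prob = 1), "\\[0, 1\\)")
})

test_that("video generation is seed-deterministic", {
  v1 <- generate_heart_video(video_preset("model-larva", seed = 9))
  v2 <- generate_heart_video(video_preset("model-larva", seed = 9))
  expect_identical(v1$stack$frames, v2$stack$frames)
  expect_identical(v1$truth$true_beat_times, v2$truth$true_beat_times)
  v3 <- generate_heart_video(video_preset("model-larva", seed = 10))
  expect_false(identical(v1$stack$frames, v3$stack$frames))
})

test_that("ground-truth pacing matches the configured rate", {
  v <- generate_heart_video(video_config(beat_hz = 3, ibi_jitter_cv = 0,
                                         seed = 1))
  expect_equal(v$truth$true_bpm, 180)
  # jitter- and drop-free beats are exactly one period apart
  expect_equal(unique(round(diff(v$truth$true_beat_times), 10)), 1 / 3)
  m <- generate_heart_video(video_config(beat_hz = 1.5, ibi_jitter_cv = 0.2,
                                         dropped_beat_prob = 0.2, seed = 2))
  expect_equal(m$truth$true_bpm, 90)
})

test_that("mean rasterised ellipse area tracks the configured baseline", {
  cfg <- video_config(beat_hz = 2, fps = 20, n_frames = 100,
                      ibi_jitter_cv = 0, noise_sd = 0, seed = 3)
  v <- generate_heart_video(cfg)
  tr <- area_trace(v$stack)
  # 10 whole cycles fit the 5 s record exactly
  expect_lt(abs(mean(tr$area_px) / cfg$area_baseline - 1), 0.02)
  # analytic series averages to the baseline as well
  expect_lt(abs(mean(v$truth$true_area_series) / cfg$area_baseline - 1),
            0.02)
})

test_that("zero pulsation yields a constant-area stack with no rhythm", {
  v <- generate_heart_video(video_config(pulsation_fraction = 0,
                                         noise_sd = 0, seed = 4))
  b <- analyze_stack(v$stack)
  expect_lt(b$n_peaks, 2)
  expect_true(b$no_rhythm)
  expect_equal(b$bpm, 0)
})

test_that("stacks round-trip through TIFF with sidecar fps", {
  v <- generate_heart_video(video_config(n_frames = 40, seed = 5))
  f <- tempfile(fileext = ".tif")
  write_stack(v$stack, f, truth = v$truth)
  back <- read_stack(f)
  expect_equal(back$fps, v$stack$fps)
  expect_equal(back$frames, v$stack$frames)
})

test_that("ECG generation is deterministic with exact clean spacing", {
  e1 <- generate_ecg(ecg_preset("adult-normal", seed = 7))
  e2 <- generate_ecg(ecg_preset("adult-normal", seed = 7))
  expect_identical(e1$trace$voltage, e2$trace$voltage)
  clean <- generate_ecg(ecg_config(noise_sd = 0, ibi_jitter_cv = 0,
                                   seed = 1))
  b <- detect_beats_ecg(clean$trace)
  expect_equal(unique(round(diff(b$peak_times), 9)), 0.6)
  expect_equal(b$bpm, 100, tolerance = 1e-9)
  expect_error(ecg_config(sample_rate = 10, beat_hz = 2), "50 x")
})

test_that("terfenadine-type ECG is slower than the normal preset", {
  normal <- generate_ecg(ecg_preset("adult-normal", seed = 8))
  terf <- generate_ecg(ecg_preset("adult-terfenadine", seed = 8))
  expect_lt(terf$truth$true_bpm, normal$truth$true_bpm)
  expect_lt(detect_beats_ecg(terf$trace)$bpm,
            detect_beats_ecg(normal$trace)$bpm)
})

test_that("fraction assay concentrates planted actives as configured", {
  cfg <- assay_sim_config(seed = 31)
  a <- generate_fraction_assay(cfg)
  expect_equal(dim(a$areas), c(10, 71))
  expect_true(all(a$areas >= 0))
  top <- order(cfg$recovery_rates, decreasing = TRUE)[1]
  share <- a$areas[top, a$actives] / sum(a$areas[, a$actives])
  expect_gte(share, 0.8)
  # determinism
  b <- generate_fraction_assay(assay_sim_config(seed = 31))
  expect_identical(a$areas, b$areas)
  expect_error(assay_sim_config(n_fractions = 3,
                                recovery_rates = c(1, 2)), "length")
  expect_error(assay_sim_config(n_compounds = 2, n_active = 3), "<=")
})

test_that("MTT plate generation reproduces the rate formula endpoints", {
  plate <- generate_mtt(n_wells = 4, od_control_mean = 0.8,
                        od_model_mean = 0.4,
                        od_tested_mean = c(A = 0.8, B = 0.4),
                        noise_sd = 0, seed = 1)
  m <- tapply(plate$od, plate$group, mean)
  expect_equal(survival_rate(m[["A"]], m[["control"]]), 100)
  expect_equal(protection_rate(m[["A"]], m[["model"]], m[["control"]]), 100)
  expect_equal(protection_rate(m[["B"]], m[["model"]], m[["control"]]), 0)
  p2 <- generate_mtt(n_wells = 4, od_control_mean = 0.8,
                     od_model_mean = 0.4,
                     od_tested_mean = c(A = 0.8, B = 0.4),
                     noise_sd = 0, seed = 1)
  expect_identical(plate, p2)
  expect_error(generate_mtt(od_control_mean = 0), "positive")
})
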