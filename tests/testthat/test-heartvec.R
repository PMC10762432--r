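# Heart-vector synthesis, beat schedules, and recording rendering.

test_that("gaussian bumps evaluate to the closed form and null sources vanish", {
  # single R bump: px(t) = exp(-t^2 / (2 * 10^2))
  amp <- matrix(0, 3, 5, dimnames = list(c("x", "y", "z"),
                                         c("P", "Q", "R", "S", "T")))
  amp["x", "R"] <- 1
  wp <- wave_params(amp, centres = c(P = -160, Q = -45, R = 0, S = 45, T = 220),
                    widths = c(P = 20, Q = 12, R = 10, S = 12, T = 40))
  hv <- synth_heart_vector(wp, fs = 500)
  for (t0 in c(-20, -10, 0, 10, 20)) {
    i <- which(hv$t == t0)
    expect_equal(unname(hv$p["x", i]), exp(-t0^2 / (2 * 10^2)),
                 tolerance = 1e-12)
  }
  expect_true(all(hv$p[c("y", "z"), ] == 0))

  amp0 <- matrix(0, 3, 5)
  wp0 <- wave_params(amp0, centres = wp$centres, widths = wp$widths)
  expect_true(all(synth_heart_vector(wp0)$p == 0))
})

test_that("the canonical cycle spans [-200, +400) ms with the R maximum at 0", {
  hv <- synth_heart_vector(default_wave_params(), fs = 500)
  expect_equal(ncol(hv$p), 300L)
  expect_equal(hv$t[1], -200)
  expect_equal(hv$t[300], 398)
  lead1 <- project_heart_vector(hv, c(1, 0, 0))
  expect_lte(abs(hv$t[which.max(lead1)]), 1000 / hv$fs)
})

test_that("invalid wave parameters are rejected", {
  amp <- default_wave_params()$amplitudes
  expect_error(wave_params(amp, c(P = -160, Q = -200, R = 0, S = 45, T = 220),
                           c(P = 20, Q = 12, R = 15, S = 12, T = 40)),
               "ordered")
  expect_error(wave_params(amp, c(P = -160, Q = -45, R = 0, S = 45, T = 220),
                           c(P = 20, Q = -1, R = 15, S = 12, T = 40)),
               "widths")
})

test_that("beat schedules are deterministic, reproducible and truncated", {
  s <- synth_beat_schedule(1, 0, 10, seed = 1)
  expect_equal(s$beat_times, 0:9)

  s1 <- synth_beat_schedule(0.85, 0.05, 60, seed = 7)
  s2 <- synth_beat_schedule(0.85, 0.05, 60, seed = 7)
  expect_identical(s1$beat_times, s2$beat_times)
  expect_true(all(diff(s1$beat_times) >= 0.35))

  expect_error(synth_beat_schedule(0.3, 0, 10), "rr_mean")
  expect_error(synth_beat_schedule(1, 0, 0.5), "duration")
})

test_that("beat count over 10 minutes matches the renewal expectation", {
  s <- synth_beat_schedule(1, 0.05, 600, seed = 42)
  n <- length(s$beat_times)
  # expectation duration/rr_mean, 3-sigma renewal band, +1 for the t=0 beat
  expect_lte(abs(n - 600 / 1), 3 * sqrt(600) * 0.05 + 1)
})

test_that("rendering is linear, reproducible and exactly repetitive when noiseless", {
  hv <- synth_heart_vector()
  sch <- synth_beat_schedule(0.8, 0, 10, seed = 1)
  lf <- lead_field_gains(c(wrist = 1))
  rec <- render_recording(hv, sch, lf, fs_out = 500, duration = 10)

  # linearity: scaling every amplitude scales the noiseless signal exactly
  wp2 <- default_wave_params()
  wp2$amplitudes <- wp2$amplitudes * 2.5
  rec2 <- render_recording(synth_heart_vector(wp2), sch, lf, fs_out = 500,
                           duration = 10)
  expect_equal(rec2$data, 2.5 * rec$data, tolerance = 1e-12)

  # true R times at the scheduled beats, within one sample
  peaks <- sapply(sch$beat_times, function(b) {
    i0 <- max(1, round(b * 500) - 5)
    i0 + which.max(rec$data[i0:min(nrow(rec$data), i0 + 10), 1]) - 1
  })
  expect_true(all(abs((peaks - 1) / 500 - sch$beat_times) <= 1 / 500))

  # exact repetition: all full windows identical
  rp <- rpeak_set(round(sch$beat_times * 500) + 1, 500)
  ws <- extract_windows(rec, "wrist", rp)
  expect_true(all(apply(ws$windows, 2, function(col) length(unique(col)) == 1)))

  # reproducibility with noise: same seeds give bit-identical recordings
  ns <- default_noise_spec("wrist", seed = 5)
  ra <- render_recording(hv, sch, lf, noise = ns, fs_out = 500, duration = 10)
  rb <- render_recording(hv, sch, lf, noise = ns, fs_out = 500, duration = 10)
  expect_identical(ra$data, rb$data)

  # unknown noise channel is a configuration error
  expect_error(render_recording(hv, sch, lf, noise = default_noise_spec("neck"),
                                fs_out = 500, duration = 10),
               "absent from lead field")
})

test_that("gain ratios 4:2:1 are recovered in downstream grand-median R amplitudes", {
  hv <- synth_heart_vector()
  sch <- synth_beat_schedule(0.85, 0.04, 120, seed = 9)
  lf <- lead_field_gains(c(wrist = 1, neck = 0.2, ear = 0.1, scalp = 0.05))
  ns <- default_noise_spec(c("wrist", "neck", "ear", "scalp"), seed = 10)
  rec <- render_recording(hv, sch, lf, noise = ns, fs_out = 500, duration = 120)
  res <- run_algorithm1(rec, n_grid = c(8L))
  amps <- sapply(c("neck", "ear", "scalp"), function(ch) {
    f <- delineate(res$grand_medians[[ch]])
    abs(f$amplitude_mv[f$wave == "R"])
  })
  expect_equal(amps[["neck"]] / amps[["ear"]], 2, tolerance = 0.05)
  expect_equal(amps[["ear"]] / amps[["scalp"]], 2, tolerance = 0.05)
})

test_that("noise generation is bit-identical under a fixed seed", {
  ns <- noise_spec(c("a", "b"), seed = 3)
  x1 <- earbeat:::synth_noise(ns, 5000, 500)
  x2 <- earbeat:::synth_noise(ns, 5000, 500)
  expect_identical(x1, x2)
  expect_error(noise_spec("a", broadband_sd = -1), "non-negative")
})
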