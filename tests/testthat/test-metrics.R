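# The four similarity metrics, cross-checked against independent oracles.

test_that("pearson matches hand values and its invariances", {
  x <- c(1, 0, 1, 0)
  expect_equal(pearson(x, c(1, 1, 0, 0)), 0)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)

  set.seed(71)
  a <- rnorm(50)
  b <- rnorm(50)
  expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  expect_equal(pearson(3 * a + 2, b), pearson(a, b), tolerance = 1e-12)
  expect_equal(pearson(-a, b), -pearson(a, b), tolerance = 1e-12)

  expect_error(pearson(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson(1:2, 1:2), "length")
})

test_that("wave amplitude ratio matches hand values and the oracle", {
  ref <- wf_from(c(P = -160, Q = -45, R = 0, S = 45, T = 220),
                 c(P = 0.1, Q = -0.3, R = 1, S = -0.35, T = 0.3))
  # self-comparison optimum
  expect_equal(as.numeric(wave_amplitude_ratio(ref, ref)), 1)

  # every test ratio doubled -> war = 2
  test2 <- ref
  test2$amplitude_mv <- ref$amplitude_mv * c(2, 2, 1, 2, 2)
  expect_equal(as.numeric(wave_amplitude_ratio(test2, ref)), 2)

  # normalized ratios (1, 1, 2, 2) -> sqrt(10/4)
  test3 <- ref
  test3$amplitude_mv <- ref$amplitude_mv * c(1, 1, 1, 2, 2)
  expect_equal(as.numeric(wave_amplitude_ratio(test3, ref)), sqrt(10 / 4))
  expect_equal(as.numeric(wave_amplitude_ratio(test3, ref)),
               oracle_war(test3$amplitude_mv[c(1, 2, 4, 5)], 1,
                          ref$amplitude_mv[c(1, 2, 4, 5)], 1),
               tolerance = 1e-12)

  # a zero reference wave is excluded with a reduced divisor and a flag
  ref0 <- ref
  ref0$amplitude_mv[ref0$wave == "Q"] <- 0
  w <- wave_amplitude_ratio(ref, ref0)
  expect_equal(attr(w, "n_waves"), 3L)
  expect_true(attr(w, "flagged"))

  refR0 <- ref
  refR0$amplitude_mv[refR0$wave == "R"] <- 0
  expect_error(wave_amplitude_ratio(ref, refR0), "R-wave")
})

test_that("wave timing error matches hand values and the oracle", {
  ref <- wf_from(c(P = -160, Q = -45, R = 0, S = 45, T = 220),
                 c(P = 0.1, Q = -0.3, R = 1, S = -0.35, T = 0.3))
  expect_equal(as.numeric(wave_timing_error(ref, ref)), 0)

  # all relative timings shifted +10 ms -> dwt = 10
  t10 <- ref
  t10$time_ms <- ref$time_ms + c(10, 10, 0, 10, 10)
  expect_equal(as.numeric(wave_timing_error(t10, ref)), 10)

  # differences (3, 4, 0, 0) ms -> 2.5 ms
  t34 <- ref
  t34$time_ms <- ref$time_ms + c(3, 4, 0, 0, 0)
  expect_equal(as.numeric(wave_timing_error(t34, ref)), 2.5)
  expect_equal(as.numeric(wave_timing_error(t34, ref)),
               oracle_dwt(t34$time_ms[c(1, 2, 4, 5)], 0,
                          ref$time_ms[c(1, 2, 4, 5)], 0),
               tolerance = 1e-12)

  # a missing wave reduces the divisor and flags the result
  miss <- ref
  miss$time_ms[miss$wave == "P"] <- NA
  d <- wave_timing_error(miss, ref)
  expect_equal(attr(d, "n_waves"), 3L)
  expect_true(attr(d, "flagged"))
})

test_that("normalized variance is zero at the optimum and recovers noise scale", {
  hv <- synth_heart_vector()
  template <- project_heart_vector(hv, c(1, 0, 0))

  wsi <- rhythm_window_set(matrix(rep(template, each = 20), nrow = 20), fs = 500)
  expect_equal(normalized_variance(wsi), 0)

  set.seed(72)
  n <- 1000
  sigma <- 0.05
  w <- matrix(rep(template, each = n), nrow = n) + rnorm(n * 300, sd = sigma)
  ws <- rhythm_window_set(w, fs = 500)
  gm <- grand_median(ws)
  dnv <- normalized_variance(ws, gm)
  expect_equal(dnv, sigma / sd(gm$values), tolerance = 0.05)

  # doubling the noise doubles the metric
  w2 <- matrix(rep(template, each = n), nrow = n) + rnorm(n * 300, sd = 2 * sigma)
  dnv2 <- normalized_variance(rhythm_window_set(w2, fs = 500))
  expect_equal(dnv2 / dnv, 2, tolerance = 0.05)

  # per-rhythm pooling stays close for homogeneous noise
  expect_equal(normalized_variance(ws, gm, per_rhythm = TRUE), dnv,
               tolerance = 0.01)

  const <- rhythm_window_set(matrix(1, nrow = 3, ncol = 300), fs = 500)
  expect_error(normalized_variance(const), "constant")
})
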