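# Window extraction, sliding medians, grand median.

test_that("window arithmetic matches the 600 ms convention", {
  # fs = 500, peak at (0-based) sample 1000 -> window covers samples 900..1199
  x <- matrix(0:(3000 - 1), ncol = 1, dimnames = list(NULL, "a"))
  rec <- recording(x, fs = 500)
  ws <- extract_windows(rec, "a", rpeak_set(1001L, 500))
  expect_equal(ncol(ws$windows), 300L)
  expect_equal(as.vector(ws$windows[1, ]), 900:1199)
  expect_equal(ws$rel_time[1], -200)
  expect_equal(ws$rel_time[300], 398)
})

test_that("peaks too close to the recording boundaries are dropped", {
  rec <- recording(matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "a")),
                   fs = 500)
  peaks <- rpeak_set(c(50L, 600L, 1200L, 1800L, 2400L, 3000L, 3600L, 4200L,
                       4500L, 4950L), 500)
  ws <- extract_windows(rec, "a", peaks)
  # first (< 0.2 fs from start) and last (> n - 0.4 fs) are excluded
  expect_equal(nrow(ws$windows), 8L)
  expect_error(extract_windows(rec, "bogus", peaks), "unknown channel")
})

test_that("the sliding-median count follows the n - N convention", {
  set.seed(51)
  ws <- rhythm_window_set(matrix(rnorm(100 * 300), nrow = 100), fs = 500)
  expect_equal(nrow(sliding_medians(ws, 2)$values), 98L)
  expect_equal(nrow(sliding_medians(ws, 99)$values), 1L)
  expect_equal(nrow(sliding_medians(ws, 100)$values), 0L)
  expect_error(sliding_medians(ws, 101), "N")
  expect_error(sliding_medians(ws, 1), "N")
})

test_that("medians of constant windows reproduce the order statistics", {
  mk <- function(vals) rhythm_window_set(matrix(rep(vals, times = 300),
                                                nrow = length(vals)), fs = 500)
  # {1, 2, 9}, N = 3 -> zero medians by the counting convention
  expect_equal(nrow(sliding_medians(mk(c(1, 2, 9)), 3)$values), 0L)
  # adding a constant-2 window: one median, value 2 everywhere
  m <- sliding_medians(mk(c(1, 2, 9, 2)), 3)
  expect_equal(nrow(m$values), 1L)
  expect_true(all(m$values == 2))
  # even N: mean of the two central order statistics
  m2 <- sliding_medians(mk(c(1, 2, 9, 2)), 2)
  expect_equal(m2$values[, 1], c(1.5, 5.5))

  # identical windows: every median equals the common window
  set.seed(52)
  v <- rnorm(300)
  wsi <- rhythm_window_set(matrix(rep(v, each = 10), nrow = 10), fs = 500)
  ms <- sliding_medians(wsi, 4)
  expect_true(all(apply(ms$values, 1, function(row) all(row == v))))
  gm <- grand_median(wsi)
  expect_equal(gm$values, v)
  expect_equal(gm$N, 10L)
})

test_that("medians are invariant to permuting windows within the block", {
  set.seed(53)
  w <- matrix(rnorm(20 * 300), nrow = 20)
  ws <- rhythm_window_set(w, fs = 500)
  wsp <- rhythm_window_set(w[c(sample(1:6), 7:20), ], fs = 500)
  expect_equal(sliding_medians(ws, 6)$values[1, ],
               sliding_medians(wsp, 6)$values[1, ])
  expect_equal(grand_median(ws)$values,
               grand_median(rhythm_window_set(w[sample(20), ], fs = 500))$values)
})

test_that("the grand median converges to the template at the median rate", {
  set.seed(54)
  hv <- synth_heart_vector()
  template <- project_heart_vector(hv, c(1, 0, 0))
  n <- 601
  sigma <- 0.05
  w <- matrix(rep(template, each = n), nrow = n) + rnorm(n * 300, sd = sigma)
  gm <- grand_median(rhythm_window_set(w, fs = 500))
  dev <- gm$values - template
  band <- 3 * 1.2533 * sigma / sqrt(n)
  expect_gte(mean(abs(dev) <= band), 0.99)
  expect_lte(sqrt(mean(dev^2)), 1.45 * sigma / sqrt(n))
})

test_that("empty window sets are rejected", {
  ws <- rhythm_window_set(matrix(numeric(0), nrow = 0, ncol = 300), fs = 500)
  expect_error(grand_median(ws), "empty")
})
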