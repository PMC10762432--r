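# Beat windows, sliding median ensembles, grand median (pipeline steps 4-5).

#' Per-beat rhythm windows for one channel
#'
#' @param windows Numeric matrix, `n_rhythms` x `T`, one 600 ms beat window
#'   per row (mV); `T` must equal `0.6 * fs`.
#' @param fs Sampling rate in Hz.
#' @param channel Source channel name.
#' @param peaks Optional R-peak sample indices the windows were cut at.
#' @return An object of class `rhythm_window_set` with a `rel_time` axis in
#'   ms spanning `[-200, +400)`.
#' @export
rhythm_window_set <- function(windows, fs, channel = NA_character_,
                              peaks = NULL) {
  windows <- as.matrix(windows)
  pre <- round(0.2 * fs)
  len <- round(0.6 * fs)
  if (ncol(windows) != len) {
    stop("windows must have 0.6 * fs = ", len, " columns", call. = FALSE)
  }
  rel_time <- (seq_len(len) - 1 - pre) * 1000 / fs
  structure(list(windows = windows, rel_time = rel_time, fs = fs,
                 channel = channel, peaks = peaks),
            class = "rhythm_window_set")
}

#' @export
print.rhythm_window_set <- function(x, ...) {
  cat(sprintf("<rhythm_window_set> %d rhythms x %d samples @ %g Hz (channel %s)\n",
              nrow(x$windows), ncol(x$windows), x$fs, x$channel))
  invisible(x)
}

#' Extract 600 ms beat windows around R-peaks
#'
#' For a peak at sample `k` the window covers samples
#' `[k - 0.2 fs, k + 0.4 fs)`. Peaks too close to the recording boundaries
#' for a full window are dropped.
#'
#' @param rec A [recording()].
#' @param channel Channel to window.
#' @param rpeaks An [rpeak_set()] detected at the same sampling rate.
#' @return A [rhythm_window_set()].
#' @export
extract_windows <- function(rec, channel, rpeaks) {
  stopifnot(inherits(rec, "recording"), inherits(rpeaks, "rpeak_set"))
  if (rpeaks$fs != rec$fs) {
    stop("rpeaks and recording sampling rates differ", call. = FALSE)
  }
  x <- get_channel(rec, channel)
  fs <- rec$fs
  pre <- round(0.2 * fs)
  post <- round(0.4 * fs)
  n <- length(x)
  ok <- rpeaks$indices - pre >= 1L & rpeaks$indices + post - 1L <= n
  peaks <- rpeaks$indices[ok]
  w <- matrix(0, nrow = length(peaks), ncol = pre + post)
  for (i in seq_along(peaks)) {
    w[i, ] <- x[(peaks[i] - pre):(peaks[i] + post - 1L)]
  }
  rhythm_window_set(w, fs = fs, channel = channel, peaks = peaks)
}

#' Median cardiac rhythm
#'
#' @param values Numeric vector of `T` samples (mV) on the window axis.
#' @param fs Sampling rate in Hz.
#' @param N Ensemble size the median was computed from.
#' @param start_beat Index of the first contributing rhythm.
#' @param channel Source channel.
#' @return An object of class `median_rhythm`.
#' @export
median_rhythm <- function(values, fs, N, start_beat = 1L,
                          channel = NA_character_) {
  pre <- round(0.2 * fs)
  rel_time <- (seq_along(values) - 1 - pre) * 1000 / fs
  structure(list(values = as.numeric(values), rel_time = rel_time, fs = fs,
                 N = as.integer(N), start_beat = as.integer(start_beat),
                 channel = channel),
            class = "median_rhythm")
}

#' Sliding ensemble medians
#'
#' For `n` available rhythms and ensemble size `N`, `n - N` median rhythms
#' are computed (the counting convention of the pipeline: for 100
#' consecutive rhythms and N = 2, 98 medians). Median `m` covers rhythms
#' `m..m+N-1`; each sample is the per-sample median of the `N` windows, and
#' for even `N` the median is the mean of the two central order statistics.
#'
#' @param ws A [rhythm_window_set()].
#' @param N Ensemble size, `2 <= N <= n_rhythms`.
#' @return An object of class `median_rhythm_set`: list with `values`
#'   (`(n - N)` x `T` matrix), `N`, `starts`, `rel_time`, `fs`, `channel`.
#' @export
sliding_medians <- function(ws, N) {
  stopifnot(inherits(ws, "rhythm_window_set"))
  n <- nrow(ws$windows)
  if (N < 2 || N > n) {
    stop("`N` must satisfy 2 <= N <= n_rhythms (= ", n, ")", call. = FALSE)
  }
  vals <- sliding_col_medians(ws$windows, as.integer(N))
  structure(list(values = vals, N = as.integer(N),
                 starts = seq_len(max(0L, n - N)),
                 rel_time = ws$rel_time, fs = ws$fs, channel = ws$channel),
            class = "median_rhythm_set")
}

#' Grand-median cardiac rhythm
#'
#' The per-sample median over all available rhythms of a channel — the
#' subject-level template (ensemble size `N = n_rhythms`).
#'
#' @param ws A [rhythm_window_set()] with at least one rhythm.
#' @return A [median_rhythm()].
#' @export
grand_median <- function(ws) {
  stopifnot(inherits(ws, "rhythm_window_set"))
  n <- nrow(ws$windows)
  if (n < 1) stop("empty window set", call. = FALSE)
  median_rhythm(col_medians_cpp(ws$windows), fs = ws$fs, N = n,
                channel = ws$channel)
}

# numeric values from a median_rhythm or plain vector
rhythm_values <- function(x) {
  if (inherits(x, "median_rhythm")) x$values else as.numeric(x)
}
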