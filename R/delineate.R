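# PQRST peak delineation of a median cardiac rhythm.
#
# Search-window scheme (all windows in ms on the beat axis, overridable):
#   R: extremum of largest |value| in [-40, +40]; polarity taken from R
#   Q: opposite-polarity extremum in [c_R - 80, c_R)
#   S: opposite-polarity extremum in (c_R, c_R + 80]
#   P: same-polarity extremum in [-200, c_Q - 20]
#   T: same-polarity extremum in [c_S + 40, +400)
# Ties resolve to the earliest sample. A wave whose window is empty after
# clamping is marked missing (NA) and propagates as such into the metrics.

#' Default delineation search windows
#'
#' @return Named list of `c(lo, hi)` windows in ms: `R` (absolute), `Q`/`S`
#'   (relative to the located R), `P` (from the window start to `c_Q + hi`),
#'   `T` (from `c_S + lo` to the window end).
#' @export
delineation_windows <- function() {
  list(R = c(-40, 40), Q = c(-80, 0), S = c(0, 80), P = c(-200, -20),
       T = c(40, 400))
}

#' Delineate the P, Q, R, S and T peaks of a median rhythm
#'
#' @param m A [median_rhythm()] (or numeric vector of samples on the
#'   canonical `[-200, +400)` ms axis).
#' @param fs Sampling rate in Hz (taken from `m` when it is a
#'   `median_rhythm`).
#' @param polarity `"auto"` (default: the sign of the located R extremum),
#'   `"+"` or `"-"`.
#' @param windows Search windows, see [delineation_windows()].
#' @return An object of class `wave_features`: data frame with columns
#'   `wave`, `time_ms`, `amplitude_mv` (signed trace values at the peaks;
#'   `NA` for missing waves) and attribute `polarity`.
#' @export
delineate <- function(m, fs = NULL, polarity = c("auto", "+", "-"),
                      windows = delineation_windows()) {
  polarity <- match.arg(polarity)
  if (inherits(m, "median_rhythm")) {
    v <- m$values
    fs <- m$fs
    t_ms <- m$rel_time
  } else {
    if (is.null(fs)) stop("`fs` required for a plain numeric rhythm", call. = FALSE)
    v <- as.numeric(m)
    pre <- round(0.2 * fs)
    t_ms <- (seq_along(v) - 1 - pre) * 1000 / fs
  }
  if (length(v) < round(0.6 * fs)) {
    stop("rhythm shorter than the canonical 600 ms window", call. = FALSE)
  }

  pick <- function(lo, hi, score) {
    idx <- which(t_ms >= lo & t_ms <= hi)
    if (length(idx) == 0) return(NA_integer_)
    idx[which.max(score[idx])]
  }

  i_r <- pick(windows$R[1], windows$R[2], abs(v))
  if (is.na(i_r)) stop("no samples in the R search window", call. = FALSE)
  pol <- switch(polarity, auto = if (v[i_r] >= 0) 1 else -1, `+` = 1, `-` = -1)
  if (polarity != "auto") {
    i_r <- pick(windows$R[1], windows$R[2], pol * v)
  }
  c_r <- t_ms[i_r]

  eps <- 1000 / fs / 2   # half-sample guard for open interval ends
  i_q <- pick(c_r + windows$Q[1], c_r - eps, -pol * v)
  i_s <- pick(c_r + eps, c_r + windows$S[2], -pol * v)
  i_p <- if (is.na(i_q)) NA_integer_ else {
    pick(windows$P[1], t_ms[i_q] + windows$P[2], pol * v)
  }
  i_t <- if (is.na(i_s)) NA_integer_ else {
    pick(t_ms[i_s] + windows$T[1], windows$T[2] - eps, pol * v)
  }

  idx <- c(P = i_p, Q = i_q, R = i_r, S = i_s, T = i_t)
  out <- data.frame(
    wave = names(idx),
    time_ms = ifelse(is.na(idx), NA_real_, t_ms[idx]),
    amplitude_mv = ifelse(is.na(idx), NA_real_, v[idx]),
    stringsAsFactors = FALSE
  )
  attr(out, "polarity") <- pol
  class(out) <- c("wave_features", "data.frame")
  out
}

#' Build wave features directly from amplitudes and timings
#'
#' Mostly useful for tests and for driving the amplitude/timing metrics from
#' externally delineated data.
#'
#' @param time_ms Named numeric vector (names among P, Q, R, S, T), ms.
#' @param amplitude_mv Named numeric vector, mV.
#' @return A `wave_features` object.
#' @export
wave_features <- function(time_ms, amplitude_mv) {
  waves <- c("P", "Q", "R", "S", "T")
  out <- data.frame(
    wave = waves,
    time_ms = as.numeric(time_ms[waves]),
    amplitude_mv = as.numeric(amplitude_mv[waves]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("wave_features", "data.frame")
  out
}

wf_get <- function(wf, wave, col) {
  wf[wf$wave == wave, col][1]
}
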