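# Filtering and resampling (pipeline steps 1-2).
#
# All filters run zero-phase (forward-backward), since wave timings are
# compared across channels and causal group delay would bias the timing
# metric; the effective order therefore doubles. Edge transients are reduced
# by odd-reflection padding (up to 3 s per side); channel means are removed
# before filtering.

# forward-backward IIR with mirror-reflection padding (robust to recordings
# that open or close mid-beat, unlike odd reflection which turns a boundary
# extremum into a DC step)
zero_phase <- function(b, a, x, fs) {
  n <- length(x)
  np <- min(n - 1L, as.integer(3 * fs))
  front <- x[(np + 1L):2L]
  back <- x[(n - 1L):(n - np)]
  xx <- c(front, x, back)
  y <- signal::filter(b, a, xx)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(np + 1L):(np + n)])
}

butter_ba <- function(order, W, type) {
  bf <- signal::butter(order, W, type = type)
  list(b = bf$b, a = bf$a)
}

# standard constrained-gain biquad notch (-3 dB bandwidth w)
notch_ba <- function(f_c, w, fs) {
  wo <- 2 * pi * f_c / fs
  bw <- 2 * pi * w / fs
  gb <- 1 / sqrt(2)
  beta <- (sqrt(1 - gb^2) / gb) * tan(bw / 2)
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(wo), 1),
       a = c(1, -2 * gain * cos(wo), 2 * gain - 1))
}

filter_channels <- function(rec, ba, channels) {
  if (is.null(channels)) channels <- rec$channels
  missing <- setdiff(channels, rec$channels)
  if (length(missing) > 0) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- rec$data
  for (ch in channels) {
    x <- data[, ch]
    data[, ch] <- zero_phase(ba$b, ba$a, x - mean(x), rec$fs)
  }
  recording(data, fs = rec$fs, annotations = rec$annotations)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Band-pass filters the named channels with an order-`order` Butterworth
#' design applied forward and backward (zero phase, length preserved). The
#' head/ear channels of the pipeline use 0.5-30 Hz; the reference channel
#' uses 0.5-95 Hz.
#'
#' @param rec A [recording()].
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param order Filter order (default 3; doubled by the zero-phase pass).
#' @param channels Channels to filter; `NULL` (default) filters all.
#' @return The filtered [recording()]; unnamed channels are untouched.
#' @export
bandpass_filter <- function(rec, f_lo, f_hi, order = 3, channels = NULL) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq)) {
    stop("band edges must satisfy 0 < f_lo < f_hi < fs/2", call. = FALSE)
  }
  filter_channels(rec, butter_ba(order, c(f_lo, f_hi) / nyq, "pass"), channels)
}

#' Zero-phase IIR notch filter
#'
#' Second-order notch with centre `f_c` and -3 dB bandwidth `w` (defaults
#' 50 Hz and 5 Hz, the powerline settings of the reference-channel chain),
#' applied forward and backward.
#'
#' @inheritParams bandpass_filter
#' @param f_c Centre frequency in Hz.
#' @param w Bandwidth in Hz.
#' @return The filtered [recording()].
#' @export
notch_filter <- function(rec, f_c = 50, w = 5, channels = NULL) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(f_c - w / 2 > 0 && f_c + w / 2 < nyq)) {
    stop("notch band must lie inside (0, fs/2)", call. = FALSE)
  }
  filter_channels(rec, notch_ba(f_c, w, rec$fs), channels)
}

#' Integer-factor downsampling with anti-alias filtering
#'
#' Zero-phase order-4 Butterworth low-pass at 80% of the target Nyquist,
#' then decimation; used to reduce 1.2 kHz recordings to 300 Hz. Annotations
#' (in seconds) are preserved.
#'
#' @param rec A [recording()].
#' @param fs_target Target rate in Hz; must divide `rec$fs`.
#' @return The resampled [recording()].
#' @export
resample_recording <- function(rec, fs_target) {
  stopifnot(inherits(rec, "recording"))
  if (fs_target > rec$fs) stop("`fs_target` exceeds the recording rate", call. = FALSE)
  k <- rec$fs / fs_target
  if (abs(k - round(k)) > 1e-9) {
    stop("`fs_target` must divide the recording rate", call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k == 1L) return(rec)
  ba <- butter_ba(4, 0.8 * (fs_target / 2) / (rec$fs / 2), "low")
  n <- nrow(rec$data)
  keep <- seq(1L, n, by = k)
  data <- matrix(0, nrow = length(keep), ncol = ncol(rec$data),
                 dimnames = list(NULL, rec$channels))
  for (ch in rec$channels) {
    x <- rec$data[, ch]
    data[, ch] <- zero_phase(ba$b, ba$a, x - mean(x), rec$fs)[keep] + mean(x)
  }
  recording(data, fs = fs_target, annotations = rec$annotations)
}
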