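# Pan-Tompkins QRS detection on the reference channel.
#
# Classic stages: 5-15 Hz bandpass, five-point derivative, squaring, 150 ms
# moving-window integration, adaptive dual thresholds with signal/noise level
# tracking, a 200 ms refractory period, T-wave discrimination inside 360 ms,
# and search-back at 1.66x the running RR average. Detections are refined to
# the local absolute maximum of the (already filtered) reference trace, which
# makes the detector invariant to polarity inversion.

#' Set of detected R-peaks
#'
#' @param indices Strictly increasing sample indices (1-based) of R maxima,
#'   at least 0.2 s apart.
#' @param fs Sampling rate in Hz.
#' @return An object of class `rpeak_set`.
#' @export
rpeak_set <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) > 1) {
    if (any(diff(indices) <= 0)) {
      stop("peak indices must be strictly increasing", call. = FALSE)
    }
    if (any(diff(indices) < 0.2 * fs)) {
      stop("peaks violate the 200 ms refractory period", call. = FALSE)
    }
  }
  structure(list(indices = indices, fs = fs), class = "rpeak_set")
}

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Pan-Tompkins R-peak detection
#'
#' @param x Numeric trace of the (filtered) reference channel, in mV.
#' @param fs Sampling rate in Hz (>= 200).
#' @param refine If `TRUE` (default), each detection is refined to the local
#'   absolute maximum of `x` within +/- 50 ms of the QRS fiducial located on
#'   the 5-15 Hz bandpassed signal.
#' @return An [rpeak_set()]. A zero-variance input yields an empty set.
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Trans. Biomed. Eng. 32(3), 230-236.
#' @export
pan_tompkins <- function(x, fs, refine = TRUE) {
  if (fs < 200) stop("`fs` must be at least 200 Hz", call. = FALSE)
  n <- length(x)
  if (n < 2 * fs) stop("signal must be at least 2 s long", call. = FALSE)
  if (sd(x) == 0) return(rpeak_set(integer(0), fs))

  ba <- butter_ba(2, c(5, 15) / (fs / 2), "pass")
  bp <- zero_phase(ba$b, ba$a, x - mean(x), fs)
  # five-point derivative, causal (2-sample delay)
  der <- as.numeric(signal::filter(c(1, 2, 0, -2, -1) * fs / 8, 1, bp))
  sq <- der^2
  w <- round(0.15 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  # candidate fiducials: local maxima of the integrated signal
  d <- diff(mwi)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0) return(rpeak_set(integer(0), fs))

  init <- mwi[seq_len(2 * fs)]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  refract <- round(0.2 * fs)
  twave_win <- round(0.36 * fs)

  accepted <- integer(0)
  acc_mwi <- numeric(0)
  rr_hist <- numeric(0)

  classify <- function(p, searchback_ok = TRUE) {
    # returns TRUE if accepted as a QRS
    thr1 <- npki + 0.25 * (spki - npki)
    last <- if (length(accepted) > 0) accepted[length(accepted)] else -Inf
    if (p - last < refract) return(FALSE)
    if (mwi[p] > thr1) {
      if (p - last < twave_win && length(acc_mwi) > 0 &&
          mwi[p] < 0.5 * acc_mwi[length(acc_mwi)]) {
        npki <<- 0.125 * mwi[p] + 0.875 * npki
        return(FALSE)
      }
      spki <<- 0.125 * mwi[p] + 0.875 * spki
      accepted <<- c(accepted, p)
      acc_mwi <<- c(acc_mwi, mwi[p])
      if (length(accepted) > 1) {
        rr_hist <<- c(rr_hist, diff(tail(accepted, 2L)))
        if (length(rr_hist) > 8) rr_hist <<- tail(rr_hist, 8L)
      }
      return(TRUE)
    }
    npki <<- 0.125 * mwi[p] + 0.875 * npki
    FALSE
  }

  for (p in cand) {
    # search-back: long gap since the last accepted QRS
    if (length(accepted) > 0 && length(rr_hist) > 0) {
      gap_limit <- 1.66 * mean(rr_hist)
      last <- accepted[length(accepted)]
      if (p - last > gap_limit) {
        thr2 <- 0.5 * (npki + 0.25 * (spki - npki))
        between <- cand[cand > last + refract & cand < p]
        if (length(between) > 0) {
          best <- between[which.max(mwi[between])]
          if (mwi[best] > thr2) {
            spki <- 0.25 * mwi[best] + 0.75 * spki
            accepted <- c(accepted, best)
            acc_mwi <- c(acc_mwi, mwi[best])
            rr_hist <- c(rr_hist, best - last)
            if (length(rr_hist) > 8) rr_hist <- tail(rr_hist, 8L)
          }
        }
      }
    }
    classify(p)
  }
  if (length(accepted) == 0) return(rpeak_set(integer(0), fs))

  # fiducial refinement: MWI peaks lag the R maximum by the integration
  # window, so search the bandpassed signal backwards, then the reference.
  back <- as.integer(round(0.2 * fs))
  fwd <- as.integer(round(0.05 * fs))
  ref50 <- as.integer(round(0.05 * fs))
  peaks <- vapply(accepted, function(p) {
    i0 <- max(1L, p - back)
    i1 <- min(n, p + fwd)
    s1 <- i0 + which.max(abs(bp[i0:i1])) - 1L
    if (!refine) return(s1)
    j0 <- max(1L, s1 - ref50)
    j1 <- min(n, s1 + ref50)
    j0 + which.max(abs(x[j0:j1])) - 1L
  }, integer(1))

  # dedupe and enforce the refractory invariant, keeping the larger peak
  ord <- order(peaks)
  peaks <- peaks[ord]
  keep <- logical(length(peaks))
  lastk <- 0L
  for (i in seq_along(peaks)) {
    if (lastk == 0L || peaks[i] - peaks[lastk] >= refract) {
      keep[i] <- TRUE
      lastk <- i
    } else if (abs(x[peaks[i]]) > abs(x[peaks[lastk]])) {
      keep[lastk] <- FALSE
      keep[i] <- TRUE
      lastk <- i
    }
  }
  rpeak_set(unique(peaks[keep]), fs)
}

#' Detect R-peaks on a recording channel
#'
#' Convenience wrapper running [pan_tompkins()] on one channel of a
#' [recording()]. Detection is only ever run on the reference channel in the
#' standard pipeline; ear/head channels are windowed at the reference R
#' times.
#'
#' @param rec A [recording()].
#' @param channel Channel name.
#' @param ... Passed to [pan_tompkins()].
#' @return An [rpeak_set()].
#' @export
detect_rpeaks <- function(rec, channel, ...) {
  pan_tompkins(get_channel(rec, channel), rec$fs, ...)
}
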