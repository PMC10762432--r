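# The four channel-similarity metrics.
#
# (i)   Pearson correlation r between a channel's median rhythm and the
#       reference grand-median. Optimum 1.
# (ii)  Wave amplitude ratio: war = sqrt((1/4) * sum_j rho_j^2) with
#       rho_j = (a_j * b_R) / (b_j * a_R), j in {P, Q, S, T}; a are the test
#       amplitudes, b the reference amplitudes. Optimum 1. Signed amplitudes
#       cancel under the square, so war is robust to channel polarity.
# (iii) Wave timing error: dwt = sqrt((1/4) * sum_j ((c_j - c_R) -
#       (d_j - d_R))^2) in ms, timings relative to the R-wave. Optimum 0.
# (iv)  Normalized variance: dnv = RMSE(all windows vs the channel's own
#       grand-median, pooled over rhythms and samples) / sd(grand-median).
#       Optimum 0.
# Metrics needing a missing or zero-reference wave average over the
# remaining waves with the divisor reduced, and flag the result.

#' Pearson correlation between a rhythm and the reference grand-median
#'
#' @param x,y Numeric vectors (or [median_rhythm()] objects) of equal length
#'   >= 3; both must be non-constant.
#' @return The product-moment correlation coefficient.
#' @export
pearson <- function(x, y) {
  x <- rhythm_values(x)
  y <- rhythm_values(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("inputs must have equal length >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

war_ratios <- function(test, ref) {
  a_r <- wf_get(test, "R", "amplitude_mv")
  b_r <- wf_get(ref, "R", "amplitude_mv")
  if (is.na(a_r) || is.na(b_r) || a_r == 0 || b_r == 0) {
    stop("R-wave amplitudes must be present and non-zero", call. = FALSE)
  }
  vapply(c("P", "Q", "S", "T"), function(j) {
    a_j <- wf_get(test, j, "amplitude_mv")
    b_j <- wf_get(ref, j, "amplitude_mv")
    if (is.na(a_j) || is.na(b_j) || b_j == 0) return(NA_real_)
    (a_j * b_r) / (b_j * a_r)
  }, numeric(1))
}

#' Wave amplitude ratio
#'
#' RMS of the four per-wave R-normalized amplitude ratios (P, Q, S, T) of the
#' test rhythm against the reference rhythm. Equals 1 when the test
#' amplitudes reproduce the reference amplitude structure.
#'
#' @param test,ref `wave_features` of the test rhythm and of the reference
#'   grand-median.
#' @return The ratio, with attribute `n_waves` giving the number of waves
#'   available; if fewer than four contributed the result carries
#'   `flagged = TRUE`.
#' @export
wave_amplitude_ratio <- function(test, ref) {
  rho <- war_ratios(test, ref)
  ok <- !is.na(rho)
  if (!any(ok)) stop("no usable waves for the amplitude ratio", call. = FALSE)
  out <- sqrt(mean(rho[ok]^2))
  attr(out, "n_waves") <- sum(ok)
  attr(out, "flagged") <- sum(ok) < 4L
  out
}

#' Wave timing error
#'
#' RMS difference (ms) of the P, Q, S and T timings relative to the R-wave
#' between the test rhythm and the reference grand-median. Equals 0 when the
#' relative timings agree.
#'
#' @inheritParams wave_amplitude_ratio
#' @return Timing error in ms, with `n_waves`/`flagged` attributes as in
#'   [wave_amplitude_ratio()].
#' @export
wave_timing_error <- function(test, ref) {
  c_r <- wf_get(test, "R", "time_ms")
  d_r <- wf_get(ref, "R", "time_ms")
  if (is.na(c_r) || is.na(d_r)) {
    stop("R-wave timings must be present", call. = FALSE)
  }
  diffs <- vapply(c("P", "Q", "S", "T"), function(j) {
    c_j <- wf_get(test, j, "time_ms")
    d_j <- wf_get(ref, j, "time_ms")
    if (is.na(c_j) || is.na(d_j)) return(NA_real_)
    (c_j - c_r) - (d_j - d_r)
  }, numeric(1))
  ok <- !is.na(diffs)
  if (!any(ok)) stop("no usable waves for the timing error", call. = FALSE)
  out <- sqrt(mean(diffs[ok]^2))
  attr(out, "n_waves") <- sum(ok)
  attr(out, "flagged") <- sum(ok) < 4L
  out
}

#' Normalized variance of a channel's rhythms
#'
#' Root-mean-square error between every individual rhythm of a channel and
#' the channel's own grand-median, pooled over all rhythms and samples under
#' one radical, divided by the standard deviation of the grand-median.
#' `per_rhythm = TRUE` instead averages per-rhythm RMSE values before
#' normalizing (the alternative pooling).
#'
#' @param ws A [rhythm_window_set()].
#' @param gm The channel grand-median; defaults to `grand_median(ws)`.
#' @param per_rhythm Pooling switch, see above.
#' @return The normalized variance (dimensionless).
#' @export
normalized_variance <- function(ws, gm = NULL, per_rhythm = FALSE) {
  stopifnot(inherits(ws, "rhythm_window_set"))
  if (is.null(gm)) gm <- grand_median(ws)
  y <- rhythm_values(gm)
  sigma_y <- sd(y)
  if (sigma_y == 0) {
    stop("grand-median is constant; normalized variance undefined", call. = FALSE)
  }
  err2 <- sweep(ws$windows, 2L, y)^2
  if (per_rhythm) {
    mean(sqrt(rowMeans(err2))) / sigma_y
  } else {
    sqrt(mean(err2)) / sigma_y
  }
}

# vectorized Pearson r of each row of M against y
row_pearson <- function(M, y) {
  cy <- y - mean(y)
  Mc <- M - rowMeans(M)
  num <- as.vector(Mc %*% cy)
  den <- sqrt(rowSums(Mc^2) * sum(cy^2))
  num / den
}
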