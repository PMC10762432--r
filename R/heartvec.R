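# Parametric heart-vector source and synthetic multichannel rendering.
#
# The heart vector is the time-varying equivalent current dipole of the heart.
# One cardiac cycle spans the half-open interval [-200, +400) ms around the
# R maximum, so at fs = 500 Hz a cycle holds exactly T = 0.6 * fs = 300 samples.

#' Gaussian parameterization of one heart-vector cycle
#'
#' Each of the five canonical ECG deflections (P, Q, R, S, T) is modelled as a
#' Gaussian bump per dipole component, so component `c` of the dipole moment is
#' `p_c(t) = sum_k alpha_kc * exp(-(t - theta_k)^2 / (2 * b_k^2))`.
#'
#' @param amplitudes 3 x 5 numeric matrix of bump amplitudes in mA*m; rows
#'   `x`, `y`, `z` (left-right, front-back, below-above), columns
#'   `P`, `Q`, `R`, `S`, `T`.
#' @param centres Named numeric vector of bump centres in ms on the cycle axis.
#'   Must satisfy `P < Q < R = 0 < S < T`.
#' @param widths Named numeric vector of bump widths (Gaussian sd) in ms,
#'   all strictly positive.
#' @return An object of class `wave_params`.
#' @seealso [default_wave_params()], [synth_heart_vector()]
#' @export
wave_params <- function(amplitudes, centres, widths) {
  waves <- c("P", "Q", "R", "S", "T")
  amplitudes <- as.matrix(amplitudes)
  if (!all(dim(amplitudes) == c(3L, 5L))) {
    stop("`amplitudes` must be a 3 x 5 matrix (components x waves)", call. = FALSE)
  }
  dimnames(amplitudes) <- list(c("x", "y", "z"), waves)
  centres <- centres[waves]
  widths <- widths[waves]
  if (anyNA(centres) || anyNA(widths)) {
    stop("`centres` and `widths` must be named for all of P, Q, R, S, T",
         call. = FALSE)
  }
  if (any(diff(centres) <= 0)) {
    stop("wave centres must be strictly ordered P < Q < R < S < T", call. = FALSE)
  }
  if (centres[["R"]] != 0) {
    stop("the R-wave centre must sit at t = 0 ms", call. = FALSE)
  }
  if (any(widths <= 0)) {
    stop("all wave widths must be > 0", call. = FALSE)
  }
  structure(list(amplitudes = amplitudes, centres = centres, widths = widths),
            class = "wave_params")
}

#' Default heart-vector wave parameters
#'
#' A fixture parameterization whose Lead-I projection has canonical
#' morphology: P at -160 ms, Q at -45 ms, R at 0 ms, S at +45 ms, T at
#' +220 ms, with amplitude ratios R:T:P of roughly 10:3:1. The y and z
#' components carry smaller, wave-specific admixtures so that distinct lead
#' vectors see highly correlated but not identical rhythms. These values are
#' declared synthetic constants, not a reconstruction of any measured subject.
#'
#' @return A [wave_params()] object.
#' @export
default_wave_params <- function() {
  amp <- rbind(
    x = c(P = 0.10, Q = -0.30, R = 1.00, S = -0.35, T = 0.30),
    y = c(P = 0.03, Q = -0.05, R = 0.20, S = -0.06, T = 0.09),
    z = c(P = -0.02, Q = 0.06, R = -0.30, S = 0.09, T = -0.08)
  )
  wave_params(
    amplitudes = amp,
    centres = c(P = -160, Q = -45, R = 0, S = 45, T = 220),
    widths = c(P = 20, Q = 12, R = 15, S = 12, T = 40)
  )
}

#' Synthesize one heart-vector cycle
#'
#' Evaluates the Gaussian bump superposition on the canonical cycle axis
#' `[-200, +400)` ms. The result is deterministic.
#'
#' @param params A [wave_params()] object.
#' @param fs Sampling rate in Hz (>= 250).
#' @return An object of class `heart_vector` with fields `fs`, `t` (ms) and
#'   `p` (3 x T dipole-moment matrix in mA*m).
#' @examples
#' hv <- synth_heart_vector(default_wave_params(), fs = 500)
#' dim(hv$p)  # 3 x 300
#' @export
synth_heart_vector <- function(params = default_wave_params(), fs = 500) {
  if (!inherits(params, "wave_params")) {
    stop("`params` must be a wave_params object", call. = FALSE)
  }
  if (fs < 250) stop("`fs` must be at least 250 Hz", call. = FALSE)
  n <- round(0.6 * fs)
  t <- -200 + (seq_len(n) - 1) * 1000 / fs
  p <- matrix(0, nrow = 3L, ncol = n, dimnames = list(c("x", "y", "z"), NULL))
  for (k in colnames(params$amplitudes)) {
    bump <- exp(-(t - params$centres[[k]])^2 / (2 * params$widths[[k]]^2))
    p <- p + params$amplitudes[, k] %o% bump
  }
  structure(list(fs = fs, t = t, p = p), class = "heart_vector")
}

#' Project a heart vector onto a lead vector
#'
#' @param hv A `heart_vector`.
#' @param lead Numeric length-3 lead vector (mV per mA*m).
#' @return Numeric trace in mV on the cycle axis.
#' @export
project_heart_vector <- function(hv, lead) {
  stopifnot(inherits(hv, "heart_vector"), length(lead) == 3L)
  as.vector(lead %*% hv$p)
}

#' Beat schedule with truncated-normal RR variability
#'
#' RR intervals are i.i.d. normal with mean `rr_mean` and sd `rr_sd`,
#' truncated below at 0.35 s (by redrawing) so consecutive 600 ms beat
#' windows cannot contain two R maxima. The first beat sits at t = 0.
#'
#' @param rr_mean Mean RR interval in seconds (> 0.4).
#' @param rr_sd RR standard deviation in seconds (>= 0).
#' @param duration Recording duration in seconds (> `rr_mean`).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return An object of class `beat_schedule` with fields `beat_times` (s),
#'   `rr_mean`, `rr_sd`, `seed`.
#' @examples
#' synth_beat_schedule(1, 0, 10, seed = 1)$beat_times  # 0, 1, ..., 9
#' @export
synth_beat_schedule <- function(rr_mean, rr_sd, duration, seed = 1L) {
  if (rr_mean <= 0.4) stop("`rr_mean` must exceed 0.4 s", call. = FALSE)
  if (rr_sd < 0) stop("`rr_sd` must be non-negative", call. = FALSE)
  if (duration <= rr_mean) {
    stop("`duration` too short for at least one full RR interval", call. = FALSE)
  }
  n_max <- ceiling(duration / 0.35) + 10L
  rr <- withr::with_seed(seed, {
    if (rr_sd == 0) {
      rep(rr_mean, n_max)
    } else {
      draws <- rnorm(n_max, rr_mean, rr_sd)
      bad <- which(draws < 0.35)
      while (length(bad) > 0) {
        draws[bad] <- rnorm(length(bad), rr_mean, rr_sd)
        bad <- which(draws < 0.35)
      }
      draws
    }
  })
  beats <- cumsum(c(0, rr))
  beats <- beats[beats < duration]
  structure(list(beat_times = beats, rr_mean = rr_mean, rr_sd = rr_sd,
                 seed = as.integer(seed)),
            class = "beat_schedule")
}

#' Channel-specific additive noise specification
#'
#' Per channel: broadband Gaussian noise (EEG/EMG-like background), a 50 Hz
#' powerline sinusoid, slow sinusoidal baseline wander, and intermittent
#' EMG-like bursts (Poisson-arriving Hann-windowed noise packets). With a
#' fixed seed and parameters the generated noise is bit-identical.
#'
#' @param channels Character vector of channel names.
#' @param broadband_sd Broadband noise sd in mV.
#' @param powerline_amp Powerline amplitude in mV.
#' @param powerline_hz Powerline frequency in Hz.
#' @param baseline_amp Baseline-wander amplitude in mV.
#' @param baseline_hz Baseline-wander frequency in Hz.
#' @param emg_burst_rate EMG burst rate in bursts per minute.
#' @param emg_burst_sd Within-burst noise sd in mV.
#' @param seed Integer seed.
#' @return An object of class `noise_spec` (a data frame with a `seed`
#'   attribute). Parameters are recycled across channels.
#' @export
noise_spec <- function(channels,
                       broadband_sd = 0.06,
                       powerline_amp = 0.02,
                       powerline_hz = 50,
                       baseline_amp = 0.05,
                       baseline_hz = 0.2,
                       emg_burst_rate = 2,
                       emg_burst_sd = 0.08,
                       seed = 1L) {
  spec <- data.frame(
    channel = as.character(channels),
    broadband_sd = broadband_sd,
    powerline_amp = powerline_amp,
    powerline_hz = powerline_hz,
    baseline_amp = baseline_amp,
    baseline_hz = baseline_hz,
    emg_burst_rate = emg_burst_rate,
    emg_burst_sd = emg_burst_sd,
    stringsAsFactors = FALSE
  )
  num <- spec[, -1L]
  if (any(num < 0)) stop("all noise parameters must be non-negative", call. = FALSE)
  if (anyDuplicated(spec$channel)) stop("duplicate channel names", call. = FALSE)
  structure(spec, seed = as.integer(seed), class = c("noise_spec", "data.frame"))
}

#' Default noise profiles for the standard channel set
#'
#' Head/ear channels share one noise level (emulating EEG and temporal-muscle
#' EMG background); the wrist reference is low-noise apart from stronger
#' powerline and baseline wander, as typical of limb leads.
#'
#' @param channels Channel names.
#' @param reference Name of the reference (wrist) channel.
#' @param seed Integer seed.
#' @param scale Multiplier applied to all noise amplitudes.
#' @return A [noise_spec()].
#' @export
default_noise_spec <- function(channels, reference = "wrist", seed = 1L,
                               scale = 1) {
  ns <- noise_spec(channels, seed = seed)
  is_ref <- ns$channel == reference
  if (any(is_ref)) {
    ns$broadband_sd[is_ref] <- 0.01
    ns$powerline_amp[is_ref] <- 0.05
    ns$baseline_amp[is_ref] <- 0.10
    ns$emg_burst_rate[is_ref] <- 0
    ns$emg_burst_sd[is_ref] <- 0
  }
  amp_cols <- c("broadband_sd", "powerline_amp", "baseline_amp", "emg_burst_sd")
  ns[amp_cols] <- ns[amp_cols] * scale
  ns
}

# Generate the noise matrix (n x channels) for a spec; deterministic in seed.
synth_noise <- function(spec, n, fs) {
  seed <- attr(spec, "seed")
  tt <- (seq_len(n) - 1) / fs
  withr::with_seed(seed, {
    out <- matrix(0, nrow = n, ncol = nrow(spec))
    colnames(out) <- spec$channel
    for (i in seq_len(nrow(spec))) {
      s <- spec[i, ]
      x <- numeric(n)
      if (s$broadband_sd > 0) x <- x + rnorm(n, 0, s$broadband_sd)
      if (s$powerline_amp > 0) {
        x <- x + s$powerline_amp * sin(2 * pi * s$powerline_hz * tt + runif(1, 0, 2 * pi))
      }
      if (s$baseline_amp > 0) {
        x <- x + s$baseline_amp * sin(2 * pi * s$baseline_hz * tt + runif(1, 0, 2 * pi)) +
          0.5 * s$baseline_amp * sin(2 * pi * 1.7 * s$baseline_hz * tt + runif(1, 0, 2 * pi))
      }
      if (s$emg_burst_rate > 0 && s$emg_burst_sd > 0) {
        n_burst <- rpois(1, s$emg_burst_rate * n / fs / 60)
        if (n_burst > 0) {
          centres <- runif(n_burst, 0, n / fs)
          lens <- runif(n_burst, 0.15, 0.4)
          for (b in seq_len(n_burst)) {
            i0 <- max(1L, round(centres[b] * fs))
            nb <- max(2L, round(lens[b] * fs))
            i1 <- min(n, i0 + nb - 1L)
            nb <- i1 - i0 + 1L
            win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nb) / (nb + 1))
            x[i0:i1] <- x[i0:i1] + win * rnorm(nb, 0, s$emg_burst_sd)
          }
        }
      }
      out[, i] <- x
    }
    out
  })
}

#' Render a multichannel recording from a heart vector
#'
#' Each channel is the lead-vector projection of the heart vector, tiled at
#' the scheduled beat times (overlap between consecutive beats is resolved by
#' summation), plus optional channel-specific noise. Off-grid beat times are
#' handled by natural-spline interpolation of the projected cycle, so beats
#' that fall on the sample grid repeat the cycle exactly.
#'
#' @param hv A `heart_vector`.
#' @param schedule A [synth_beat_schedule()] result.
#' @param lead_field A [lead_field_from_layout()] or [lead_field_gains()]
#'   object (channels to render).
#' @param noise Optional [noise_spec()]; its channels must all be present in
#'   the lead field.
#' @param fs_out Output sampling rate in Hz: 300, 500 or 1200.
#' @param duration Duration in seconds; defaults to the span of the schedule
#'   plus one window.
#' @return A [recording()] carrying the true beat times as annotations.
#' @export
render_recording <- function(hv, schedule, lead_field, noise = NULL,
                             fs_out = hv$fs, duration = NULL) {
  stopifnot(inherits(hv, "heart_vector"), inherits(schedule, "beat_schedule"),
            inherits(lead_field, "lead_field"))
  if (!fs_out %in% c(300, 500, 1200)) {
    stop("`fs_out` must be one of 300, 500, 1200 Hz", call. = FALSE)
  }
  if (is.null(duration)) duration <- max(schedule$beat_times) + 0.6
  if (!is.null(noise)) {
    missing <- setdiff(noise$channel, lead_field$channels)
    if (length(missing) > 0) {
      stop("noise channels absent from lead field: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  n <- round(duration * fs_out)
  tt <- (seq_len(n) - 1) / fs_out
  beats <- schedule$beat_times[schedule$beat_times < duration]
  # snap beats that sit on the sample grid (within float epsilon) so that
  # grid-aligned schedules repeat the cycle bit-exactly
  near <- abs(beats * fs_out - round(beats * fs_out)) < 1e-6
  beats[near] <- round(beats[near] * fs_out) / fs_out
  chans <- lead_field$channels
  data <- matrix(0, nrow = n, ncol = length(chans), dimnames = list(NULL, chans))
  for (ch in chans) {
    template <- as.vector(lead_field$leads[ch, ] %*% hv$p)
    sf <- splinefun(hv$t, template, method = "natural")
    pre <- round(0.2 * fs_out)
    post <- round(0.4 * fs_out)
    x <- numeric(n)
    for (b in beats) {
      on_grid <- abs(b * fs_out - round(b * fs_out)) < 1e-6
      if (on_grid && fs_out == hv$fs) {
        # grid-aligned beat at the source rate: index the cycle directly so
        # identical beats repeat bit-exactly
        k <- as.integer(round(b * fs_out))
        i0 <- max(1L, k - pre + 1L)
        i1 <- min(n, k + post)
        if (i1 < i0) next
        j <- (i0:i1) - 1L - k          # sample offsets in [-pre, post)
        x[i0:i1] <- x[i0:i1] + template[j + pre + 1L]
      } else {
        # half-sample epsilon guards keep the window exactly half-open
        i0 <- max(1L, as.integer(ceiling((b - 0.2) * fs_out - 1e-6)) + 1L)
        i1 <- min(n, as.integer(floor((b + 0.4) * fs_out + 1e-6)) + 1L)
        if (i1 < i0) next
        rel <- (tt[i0:i1] - b) * 1000
        keep <- rel >= -200 - 1e-6 & rel < 400 - 1e-6
        if (any(keep)) {
          idx <- (i0:i1)[keep]
          x[idx] <- x[idx] + sf(rel[keep])
        }
      }
    }
    data[, ch] <- x
  }
  if (!is.null(noise)) {
    nz <- synth_noise(noise, n, fs_out)
    data[, noise$channel] <- data[, noise$channel, drop = FALSE] + nz
  }
  recording(data, fs = fs_out, annotations = beats)
}
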