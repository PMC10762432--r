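# End-to-end pipeline: filter -> detect -> window -> ensemble -> delineate
# -> metrics, and the metric-vs-ensemble-size experiment over synthetic
# subjects.

#' Experiment plan for synthetic multi-subject runs
#'
#' Subjects are parameter draws around the generator defaults: heart rate
#' uniform in `hr_range` bpm, a common amplitude scale in `amp_jitter` and a
#' noise scale in `noise_jitter`, one seed per subject. Channel gains are
#' fixed by the plan, so gain orderings (e.g. neck:ear:scalp = 4:2:1) hold
#' exactly for every subject.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param channels Named numeric vector of channel gains (mV per unit source
#'   along each channel's lead direction); must include the reference.
#' @param reference Reference channel name (the Lead I equivalent).
#' @param duration Recording duration per subject in seconds.
#' @param fs Acquisition sampling rate (500, or 1200 for the driving-style
#'   protocol).
#' @param fs_analysis Optional analysis rate; when given (e.g. 300 for
#'   1200 Hz acquisitions) recordings are downsampled before filtering.
#' @param n_grid Ensemble sizes to evaluate.
#' @param seed Base integer seed; per-subject seeds are derived from it.
#' @param hr_range Heart-rate range in bpm.
#' @param amp_jitter,noise_jitter Ranges of the per-subject amplitude and
#'   noise scale factors.
#' @param directions Optional channels x 3 lead-direction matrix; defaults
#'   to [default_lead_directions()].
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(n_subjects = 5,
                            channels = c(wrist = 1.0, neck = 0.2, ear = 0.1,
                                         scalp = 0.05),
                            reference = "wrist",
                            duration = 600,
                            fs = 500,
                            fs_analysis = NULL,
                            n_grid = default_n_grid(),
                            seed = 1L,
                            hr_range = c(55, 85),
                            amp_jitter = c(0.8, 1.2),
                            noise_jitter = c(0.7, 1.3),
                            directions = NULL) {
  if (!reference %in% names(channels)) {
    stop("`channels` must include the reference channel", call. = FALSE)
  }
  if (is.null(directions)) directions <- default_lead_directions(names(channels))
  structure(list(n_subjects = as.integer(n_subjects), channels = channels,
                 reference = reference, duration = duration, fs = fs,
                 fs_analysis = fs_analysis, n_grid = as.integer(n_grid),
                 seed = as.integer(seed), hr_range = hr_range,
                 amp_jitter = amp_jitter, noise_jitter = noise_jitter,
                 directions = directions),
            class = "experiment_plan")
}

#' Default lead directions for the standard channel vocabulary
#'
#' The reference (wrist) lead lies along the x (left-right) axis; head and
#' ear channels are tilted slightly away from it, emulating the
#' near-parallel projection plane shared by neck, ear and scalp channels.
#'
#' @param channels Channel names.
#' @return channels x 3 matrix of (unnormalized) lead directions.
#' @export
default_lead_directions <- function(channels) {
  tilts <- list(
    wrist = c(1, 0, 0),
    neck = c(1, 0.04, -0.06),
    ear = c(1, 0.08, -0.12),
    left_ear = c(1, 0.08, -0.12),
    right_ear = c(1, -0.08, -0.12),
    cross_ear = c(1, 0.02, -0.05),
    scalp = c(1, 0.12, -0.20)
  )
  out <- t(vapply(channels, function(ch) {
    if (ch %in% names(tilts)) tilts[[ch]] else c(1, 0, 0)
  }, numeric(3)))
  dimnames(out) <- list(channels, c("x", "y", "z"))
  out
}

subject_seed <- function(plan, i) {
  as.integer((plan$seed + 104729 * i) %% (.Machine$integer.max - 1L)) + 1L
}

#' Synthesize one subject's recording under a plan
#'
#' @param plan An [experiment_plan()].
#' @param i Subject index (1-based).
#' @return A [recording()] at the plan's acquisition rate.
#' @export
synth_subject_recording <- function(plan, i) {
  stopifnot(inherits(plan, "experiment_plan"))
  sseed <- subject_seed(plan, i)
  draws <- withr::with_seed(sseed, {
    list(hr = runif(1, plan$hr_range[1], plan$hr_range[2]),
         amp = runif(1, plan$amp_jitter[1], plan$amp_jitter[2]),
         noise = runif(1, plan$noise_jitter[1], plan$noise_jitter[2]))
  })
  wp <- default_wave_params()
  wp$amplitudes <- wp$amplitudes * draws$amp
  hv <- synth_heart_vector(wp, fs = 500)
  schedule <- synth_beat_schedule(rr_mean = 60 / draws$hr, rr_sd = 0.04,
                                  duration = plan$duration, seed = sseed + 1L)
  lf <- lead_field_gains(plan$channels, plan$directions)
  ns <- default_noise_spec(names(plan$channels), reference = plan$reference,
                           seed = sseed + 2L, scale = draws$noise)
  render_recording(hv, schedule, lf, noise = ns, fs_out = plan$fs,
                   duration = plan$duration)
}

#' Run the full signal-processing pipeline on one recording
#'
#' Steps: band-pass head/ear channels 0.5-30 Hz (order-3 Butterworth,
#' zero-phase); band-pass the reference 0.5-95 Hz and notch it at 50 Hz
#' (5 Hz bandwidth); detect R-peaks on the filtered reference with
#' Pan-Tompkins; cut 600 ms windows around the reference R times in every
#' channel (peaks within `edge_trim` s of the recording boundaries are
#' dropped against filter transients); compute sliding median rhythms over
#' the ensemble-size grid; delineate; and score all four metrics against the
#' reference grand-median. Metrics (ii)-(iii) compare each median rhythm's
#' wave structure to the reference grand-median's; metric (iv) compares a
#' channel's individual rhythms to that channel's own grand-median. Per-
#' median metrics are averaged within the recording.
#'
#' @param rec A [recording()] containing the reference channel.
#' @param reference Reference channel name.
#' @param channels Test channels; default all channels (including the
#'   reference itself, whose row then shows the self-comparison optima).
#' @param n_grid Ensemble sizes; values exceeding the available rhythm count
#'   are skipped with a warning.
#' @param ecg_band,ref_band Band edges (Hz) for head/ear and reference
#'   channels.
#' @param notch Centre frequency and bandwidth (Hz) of the reference notch.
#' @param order Butterworth order.
#' @param edge_trim Seconds trimmed from both recording ends before beat
#'   selection.
#' @return An object of class `algorithm1_result`: list with `report` (one
#'   row per channel per N: `n_medians`, `r`, `war`, `dwt_ms`, `dnv`),
#'   `rpeaks`, `ref_grand_median`, `grand_medians`, `n_rhythms`.
#' @export
run_algorithm1 <- function(rec, reference = "wrist", channels = NULL,
                           n_grid = default_n_grid(),
                           ecg_band = c(0.5, 30), ref_band = c(0.5, 95),
                           notch = c(50, 5), order = 3, edge_trim = 1) {
  stopifnot(inherits(rec, "recording"))
  if (!reference %in% rec$channels) {
    stop("reference channel '", reference, "' not in recording", call. = FALSE)
  }
  if (is.null(channels)) channels <- rec$channels
  head_ch <- setdiff(rec$channels, reference)
  if (length(head_ch) > 0) {
    rec <- bandpass_filter(rec, ecg_band[1], ecg_band[2], order = order,
                           channels = head_ch)
  }
  rec <- bandpass_filter(rec, ref_band[1], ref_band[2], order = order,
                         channels = reference)
  rec <- notch_filter(rec, notch[1], notch[2], channels = reference)

  rpeaks <- detect_rpeaks(rec, reference)
  if (length(rpeaks$indices) == 0) stop("no beats detected", call. = FALSE)
  lo <- edge_trim * rec$fs
  hi <- nrow(rec$data) - edge_trim * rec$fs
  rpeaks <- rpeak_set(rpeaks$indices[rpeaks$indices > lo & rpeaks$indices < hi],
                      rec$fs)
  if (length(rpeaks$indices) == 0) stop("no beats detected", call. = FALSE)

  ws_ref <- extract_windows(rec, reference, rpeaks)
  ref_gm <- grand_median(ws_ref)
  ref_feat <- delineate(ref_gm)
  y <- ref_gm$values

  rows <- list()
  gms <- list()
  for (ch in channels) {
    ws <- extract_windows(rec, ch, rpeaks)
    n <- nrow(ws$windows)
    gm_ch <- grand_median(ws)
    gms[[ch]] <- gm_ch
    dnv <- normalized_variance(ws, gm_ch)
    for (N in n_grid) {
      if (N > n - 1L) {
        warning("skipping N = ", N, " for channel '", ch,
                "' (only ", n, " rhythms)", call. = FALSE)
        next
      }
      ms <- sliding_medians(ws, N)
      r_i <- row_pearson(ms$values, y)
      war_i <- dwt_i <- rep(NA_real_, nrow(ms$values))
      for (m in seq_len(nrow(ms$values))) {
        feat <- tryCatch(delineate(median_rhythm(ms$values[m, ], ws$fs, N)),
                         error = function(e) NULL)
        if (is.null(feat)) next
        war_i[m] <- tryCatch(as.numeric(wave_amplitude_ratio(feat, ref_feat)),
                             error = function(e) NA_real_)
        dwt_i[m] <- tryCatch(as.numeric(wave_timing_error(feat, ref_feat)),
                             error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, N = N, n_medians = nrow(ms$values),
        r = mean(r_i), war = mean(war_i, na.rm = TRUE),
        dwt_ms = mean(dwt_i, na.rm = TRUE), dnv = dnv,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(report = do.call(rbind, rows), rpeaks = rpeaks,
                 ref_grand_median = ref_gm, grand_medians = gms,
                 n_rhythms = nrow(ws_ref$windows)),
            class = "algorithm1_result")
}

#' Metric-vs-ensemble-size experiment over synthetic subjects
#'
#' Synthesizes each subject under the plan, runs [run_algorithm1()], and
#' averages the four metrics over subjects per channel and ensemble size.
#'
#' @param plan An [experiment_plan()].
#' @return An object of class `metrics_report`: list with `summary`
#'   (inter-subject means per channel x N), `per_subject` (all rows with a
#'   `subject` column) and the `plan`.
#' @export
run_metric_vs_N <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  per <- list()
  for (i in seq_len(plan$n_subjects)) {
    rec <- synth_subject_recording(plan, i)
    if (!is.null(plan$fs_analysis) && plan$fs_analysis != plan$fs) {
      rec <- resample_recording(rec, plan$fs_analysis)
    }
    res <- run_algorithm1(rec, reference = plan$reference,
                          n_grid = plan$n_grid)
    rep_i <- res$report
    rep_i$subject <- i
    per[[i]] <- rep_i
  }
  per <- do.call(rbind, per)
  summary <- stats::aggregate(
    per[, c("r", "war", "dwt_ms", "dnv")],
    by = list(channel = per$channel, N = per$N), FUN = mean
  )
  summary <- summary[order(summary$channel, summary$N), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, per_subject = per, plan = plan),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d subjects, %d channels, N grid of %d\n",
              x$plan$n_subjects, length(unique(x$summary$channel)),
              length(unique(x$summary$N))))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Simulated-channel benchmark
#'
#' Computes metrics (i)-(iii) between each channel's noiseless simulated
#' rhythm (the lead-field projection of the heart vector) and the simulated
#' reference rhythm — the volume-conduction benchmark against which measured
#' rhythms are interpreted.
#'
#' @param hv A `heart_vector` (default: the default parameterization).
#' @param lf A `lead_field` (default: from [default_electrode_layout()]).
#' @param reference Reference channel name.
#' @param channels Channels to score; default all in `lf`.
#' @return Data frame with columns `channel`, `r`, `war`, `dwt_ms` and
#'   `r_amplitude_mv` (the simulated R amplitude).
#' @export
run_simulation_benchmark <- function(hv = synth_heart_vector(),
                                     lf = lead_field_from_layout(default_electrode_layout()),
                                     reference = "wrist", channels = NULL) {
  if (is.null(channels)) channels <- lf$channels
  ref_trace <- simulate_channel_rhythm(hv, lf, reference)
  ref_feat <- delineate(ref_trace, fs = hv$fs)
  rows <- lapply(channels, function(ch) {
    trace <- simulate_channel_rhythm(hv, lf, ch)
    feat <- delineate(trace, fs = hv$fs)
    data.frame(channel = ch,
               r = pearson(trace, ref_trace),
               war = as.numeric(wave_amplitude_ratio(feat, ref_feat)),
               dwt_ms = as.numeric(wave_timing_error(feat, ref_feat)),
               r_amplitude_mv = abs(wf_get(feat, "R", "amplitude_mv")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
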