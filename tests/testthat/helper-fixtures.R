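# Shared fixtures (built once per run) and independent metric oracles.

fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = fx_cache)) {
    assign(name, builder(), envir = fx_cache)
  }
  get(name, envir = fx_cache)
}

# standard gain lead field, leads exactly parallel (no tilts)
fx_gain_lf <- function() {
  lead_field_gains(c(wrist = 1.0, neck = 0.2, ear = 0.1, scalp = 0.05))
}

# 120 s noiseless recording, beats on the sample grid (RR = 0.8 s at 500 Hz)
fx_noiseless_rec <- function() {
  fx("noiseless_rec", function() {
    hv <- synth_heart_vector()
    sch <- synth_beat_schedule(0.8, 0, 120, seed = 1)
    render_recording(hv, sch, fx_gain_lf(), noise = NULL, fs_out = 500,
                     duration = 120)
  })
}

fx_noiseless_res <- function() {
  fx("noiseless_res", function() {
    run_algorithm1(fx_noiseless_rec(), n_grid = c(2L, 8L, 32L))
  })
}

# one 10-minute synthetic subject under the default plan, full ensemble grid
fx_subject_res <- function() {
  fx("subject_res", function() {
    plan <- experiment_plan(n_subjects = 1, seed = 11)
    rec <- synth_subject_recording(plan, 1)
    run_algorithm1(rec)
  })
}

# --- independent brute-force oracles for the similarity metrics ---------
# Coded from the defining formulas with explicit loops, separately from the
# package implementations.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_war <- function(a, a_r, b, b_r) {
  s <- 0
  for (j in seq_along(a)) s <- s + ((a[j] * b_r) / (b[j] * a_r))^2
  sqrt(s / length(a))
}

oracle_dwt <- function(c_j, c_r, d_j, d_r) {
  s <- 0
  for (j in seq_along(c_j)) s <- s + ((c_j[j] - c_r) - (d_j[j] - d_r))^2
  sqrt(s / length(c_j))
}

# wave_features helper for metric tests
wf_from <- function(times, amps) {
  wave_features(time_ms = times, amplitude_mv = amps)
}
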