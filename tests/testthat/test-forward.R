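# Dipole forward model: identities, lead fields, simulated rhythms.

test_that("dipole potential satisfies the closed form and its symmetries", {
  p <- c(0, 0, 1)
  # hand evaluation: phi = 1e-3 * 1 / (4 pi * 0.2 * 0.1^2) V = 39.789 mV
  expect_equal(dipole_potential(p, c(0, 0, 0), c(0, 0, 100), 0.2),
               1e-3 / (4 * pi * 0.2 * 0.1^2) * 1e3, tolerance = 1e-12)

  # orthogonality: p perpendicular to the displacement gives zero
  expect_equal(dipole_potential(c(1, 0, 0), c(0, 0, 0), c(0, 0, 100), 0.2), 0)

  # antisymmetry p -> -p
  r_obs <- c(30, -40, 90)
  expect_identical(dipole_potential(-p, c(0, 0, 0), r_obs, 0.2),
                   -dipole_potential(p, c(0, 0, 0), r_obs, 0.2))

  # pure dipole decay: doubling the distance scales the potential by 1/4
  phi1 <- dipole_potential(p, c(0, 0, 0), r_obs, 0.2)
  phi2 <- dipole_potential(p, c(0, 0, 0), 2 * r_obs, 0.2)
  expect_equal(phi2, phi1 / 4, tolerance = 1e-9)

  expect_error(dipole_potential(p, c(0, 0, 0), c(0, 0, 0.5), 0.2), "1 mm")
})

test_that("lead fields respect terminal swap, degeneracy and distance ordering", {
  lay <- default_electrode_layout()
  lf <- lead_field_from_layout(lay)

  # terminal swap negates the lead vector exactly
  lay_sw <- lay
  lay_sw$channels$ear <- list(pos = lay$channels$ear$neg,
                              neg = lay$channels$ear$pos)
  lf_sw <- lead_field_from_layout(lay_sw)
  expect_identical(lf_sw$leads["ear", ], -lf$leads["ear", ])

  # coincident terminals give the zero lead vector
  lay0 <- electrode_layout(lay$electrodes,
                           list(z = list(pos = "left concha", neg = "left concha")))
  expect_true(all(lead_field_from_layout(lay0)$leads == 0))

  # neck electrodes are nearer the dipole, so the projected signal is larger
  hv <- synth_heart_vector()
  p_hat <- hv$p[, which.max(project_heart_vector(hv, c(1, 0, 0)))]
  p_hat <- p_hat / sqrt(sum(p_hat^2))
  expect_gt(abs(sum(lf$leads["neck", ] * p_hat)),
            abs(sum(lf$leads["ear", ] * p_hat)))

  expect_error(lead_field_from_layout(
    electrode_layout(lay$electrodes, list(bad = list(pos = "nope", neg = "left helix")))),
    "unknown electrode")
})

test_that("simulated rhythms superpose, track the reference, and order by attenuation", {
  lay <- default_electrode_layout()
  lf <- lead_field_from_layout(lay)
  hv <- synth_heart_vector()

  # zero lead vector -> identically zero trace
  lf0 <- lead_field_gains(c(null = 0))
  expect_true(all(simulate_channel_rhythm(hv, lf0, "null") == 0))

  # superposition: simulate(hv1 + hv2) = simulate(hv1) + simulate(hv2)
  wp_a <- default_wave_params()
  wp_b <- default_wave_params()
  wp_a$amplitudes[, c("Q", "S")] <- 0
  wp_b$amplitudes[, c("P", "R", "T")] <- 0
  hv_a <- synth_heart_vector(wp_a)
  hv_b <- synth_heart_vector(wp_b)
  expect_equal(simulate_channel_rhythm(hv_a, lf, "ear") +
                 simulate_channel_rhythm(hv_b, lf, "ear"),
               simulate_channel_rhythm(hv, lf, "ear"), tolerance = 1e-12)

  # parallel lead vectors give perfectly correlated rhythms
  lf_par <- lead_field_gains(c(a = 1, b = 0.3))
  expect_equal(pearson(simulate_channel_rhythm(hv, lf_par, "a"),
                       simulate_channel_rhythm(hv, lf_par, "b")), 1)

  # neck/ear/scalp all correlate with the reference while amplitudes decay
  ref <- simulate_channel_rhythm(hv, lf, "wrist")
  amps <- sapply(c("neck", "ear", "scalp"), function(ch) {
    trace <- simulate_channel_rhythm(hv, lf, ch)
    expect_gt(pearson(trace, ref), 0.95)
    max(abs(trace))
  })
  expect_true(amps[["neck"]] > amps[["ear"]] && amps[["ear"]] > amps[["scalp"]])

  # cross-ear spans a larger distance than a single ear
  expect_gt(max(abs(simulate_channel_rhythm(hv, lf, "cross_ear"))),
            max(abs(simulate_channel_rhythm(hv, lf, "left_ear"))))

  expect_error(simulate_channel_rhythm(hv, lf, "bogus"), "unknown channel")
})

test_that("far-field decay: doubling all electrode distances quarters every channel", {
  lay <- default_electrode_layout()
  lay2 <- electrode_layout(lay$electrodes * 2, lay$channels)
  hv <- synth_heart_vector()
  lf1 <- lead_field_from_layout(lay)
  lf2 <- lead_field_from_layout(lay2)
  for (ch in lf1$channels) {
    t1 <- simulate_channel_rhythm(hv, lf1, ch)
    t2 <- simulate_channel_rhythm(hv, lf2, ch)
    expect_equal(t2, t1 / 4, tolerance = 1e-9)
  }
})
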