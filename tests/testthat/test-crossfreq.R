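test_that("modulation index hits its entropy extremes", {
  ph <- seq(0, 2 * pi, length.out = 20001)[-1]
  # constant envelope: uniform distribution, MI = 0
  mr <- modulation_index(ph, rep(2, length(ph)))
  expect_equal(mr$mi, 0, tolerance = 1e-12)
  expect_equal(sum(mr$bins$p), 1, tolerance = 1e-9)
  # all amplitude in one bin: MI = 1
  env1 <- as.numeric(ph < 2 * pi / 18)
  expect_equal(modulation_index(ph, env1)$mi, 1, tolerance = 1e-12)
})

test_that("modulation index matches the analytic binning oracle", {
  ph <- seq(0, 2 * pi, length.out = 360001)[-1]
  env <- 1 + cos(ph - pi / 2)
  mr <- modulation_index(ph, env)
  expect_equal(mr$mi, mi_oracle_cosine(1, 1, pi / 2), tolerance = 1e-4)
  expect_equal(mr$preferred_phase_rad, pi / 2, tolerance = 2 * pi / 18)
})

test_that("MI is invariant to envelope scaling; phase offsets move the preferred phase", {
  set.seed(12)
  ph <- runif(20000, 0, 2 * pi)
  env <- 1 + 0.6 * cos(ph - 1)
  m0 <- modulation_index(ph, env)
  m_scaled <- modulation_index(ph, 10 * env)
  expect_equal(m0$mi, m_scaled$mi, tolerance = 1e-12)
  m_shift <- modulation_index(ph + 0.7, env)
  expect_equal(m_shift$mi, m0$mi, tolerance = 0.02 * max(m0$mi, 1e-6))
  shift <- (m_shift$preferred_phase_rad - m0$preferred_phase_rad) %% (2 * pi)
  expect_equal(shift, 0.7, tolerance = 2 * pi / 18)
})

test_that("degenerate envelopes are rejected or flagged", {
  ph <- seq(0, 2 * pi, length.out = 5001)[-1]
  expect_error(modulation_index(ph, rep(0, length(ph))), "zero")
  expect_error(modulation_index(ph[1:50], rep(1, 50)), "too few")
  # phases missing a bin: filled with zero and flagged
  ph_gap <- ph[ph > 2 * pi / 18 & ph < 2 * pi - 1e-9]
  expect_warning(mr <- modulation_index(ph_gap, rep(1, length(ph_gap))),
                 "empty")
  expect_equal(mr$n_empty_bins, 1)
})

test_that("pipeline-recovered coupling tracks kappa and clears the surrogate floor", {
  mis <- vapply(c(0, 0.5, 1), function(k) {
    p <- sim_params(duration_s = 60, coupling = k, run_to_rest_p = 0,
                    rest_to_run_p = 1, ripple_rate_hz = 0)
    ses <- simulate_session(p, seed = 14)
    th <- analytic_signal(bandpass_zero_phase(ses$hpc, "theta"), FS)
    lg <- analytic_signal(bandpass_zero_phase(ses$hpc, "cfc_lowgamma"), FS)
    ok <- th$edge_valid & lg$edge_valid
    modulation_index(th$phase[ok], lg$envelope[ok])$mi
  }, numeric(1))
  expect_true(all(diff(mis) > 0))

  # strong coupling beats its surrogate threshold; preferred phase recovered
  p1 <- sim_params(duration_s = 60, coupling = 1, run_to_rest_p = 0,
                   rest_to_run_p = 1, ripple_rate_hz = 0)
  ses <- simulate_session(p1, seed = 15)
  th <- analytic_signal(bandpass_zero_phase(ses$hpc, "theta"), FS)
  lg <- analytic_signal(bandpass_zero_phase(ses$hpc, "cfc_lowgamma"), FS)
  ok <- th$edge_valid & lg$edge_valid
  mr <- modulation_index(th$phase[ok], lg$envelope[ok])
  thr <- mi_surrogate_threshold(th$phase[ok], lg$envelope[ok],
                                n_surrogates = 100, seed = 1, rate = FS)
  expect_gt(mr$mi, thr)
  err <- abs(lfpkit:::wrap_pi(mr$preferred_phase_rad - pi / 2))
  expect_lt(err * 180 / pi, 20)

  expect_error(mi_surrogate_threshold(th$phase[ok], lg$envelope[ok],
                                      n_surrogates = 0), "positive")
})

test_that("surrogate threshold is deterministic given its seed", {
  set.seed(16)
  ph <- runif(20000, 0, 2 * pi)
  env <- abs(rnorm(20000)) + 0.1
  t1 <- mi_surrogate_threshold(ph, env, n_surrogates = 50, seed = 9, rate = FS)
  t2 <- mi_surrogate_threshold(ph, env, n_surrogates = 50, seed = 9, rate = FS)
  expect_identical(as.numeric(t1), as.numeric(t2))
})
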