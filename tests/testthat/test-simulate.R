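test_that("locomotion chain respects degenerate transition probabilities", {
  p_rest <- sim_params(duration_s = 60, rest_to_run_p = 0, run_to_rest_p = 1)
  out <- simulate_position(p_rest, seed = 1)
  expect_equal(unique(out$states$state), "rest")
  vel <- compute_velocity(out$position)
  expect_true(all(vel$speed_cm_s < 0.5))

  p_run <- sim_params(duration_s = 60, run_to_rest_p = 0, rest_to_run_p = 1)
  out2 <- simulate_position(p_run, seed = 1)
  expect_equal(unique(out2$states$state), "run")
})

test_that("pure-run trace moves at the commanded speed", {
  p <- sim_params(duration_s = 120, run_to_rest_p = 0, rest_to_run_p = 1,
                  run_speed_cm_s = 10)
  out <- simulate_position(p, seed = 5)
  vel <- compute_velocity(out$position)
  m <- mean(vel$speed_cm_s[100:(nrow(vel) - 100)])
  expect_equal(m, 10, tolerance = 0.05)
})

test_that("state intervals tile the session and simulation is deterministic", {
  p <- sim_params(duration_s = 90)
  a <- simulate_position(p, seed = 3)
  b <- simulate_position(p, seed = 3)
  expect_identical(a, b)
  expect_equal(a$states$start_s[1], 0)
  expect_equal(max(a$states$end_s), 90)
  expect_equal(a$states$start_s[-1], a$states$end_s[-nrow(a$states)])

  sa <- simulate_session(p, seed = 3)
  sb <- simulate_session(p, seed = 3)
  expect_identical(sa$hpc$voltage, sb$hpc$voltage)
  expect_identical(sa$pfc$voltage, sb$pfc$voltage)
  expect_identical(sa$truth$ripples, sb$truth$ripples)
})

test_that("all-zero amplitudes yield all-zero signals", {
  p <- sim_params(duration_s = 20, theta_amp_run = 0, theta_amp_rest = 0,
                  lowgamma_amp = 0, highgamma_amp = 0, ripple_rate_hz = 0,
                  line_noise_amp = 0, pink_noise_sd = 0)
  ses <- simulate_session(p, seed = 1)
  expect_true(all(ses$hpc$voltage == 0))
  expect_true(all(ses$pfc$voltage == 0))
})

test_that("ripple events respect rest intervals, spacing, and Poisson count", {
  p <- sim_params(duration_s = 600, ripple_rate_hz = 0.3,
                  run_to_rest_p = 1, rest_to_run_p = 0)
  ses <- simulate_session(p, seed = 9)
  tr <- ses$truth$ripples
  rest <- ses$truth$states[ses$truth$states$state == "rest", ]
  in_rest <- vapply(tr$onset_s, function(t0) {
    any(t0 >= rest$start_s & t0 < rest$end_s)
  }, logical(1))
  expect_true(all(in_rest))
  expect_true(all(diff(tr$onset_s) >= 0.2))
  # count within the 95% interval of a Poisson at the nominal rate
  lam <- 0.3 * 600
  expect_gt(nrow(tr), stats::qpois(0.025, lam))
  expect_lt(nrow(tr), stats::qpois(0.975, lam))
})

test_that("simulated hpc spectrum peaks at theta during run", {
  p <- sim_params(duration_s = 120, run_to_rest_p = 0, rest_to_run_p = 1)
  ses <- simulate_session(p, seed = 2)
  psd <- multitaper_psd(ses$hpc$voltage, rate = FS)
  sel <- psd$freq_hz >= 1 & psd$freq_hz <= 200
  pk <- psd$freq_hz[sel][which.max(psd$power[sel])]
  expect_equal(pk, 7, tolerance = 0.25)
})

test_that("ripple-band energy is confined to rest", {
  p <- sim_params(duration_s = 300, ripple_rate_hz = 0.5)
  ses <- simulate_session(p, seed = 4)
  st <- ses$truth$states
  band <- bandpass_zero_phase(ses$hpc$voltage, "ripple", rate = FS)
  tt <- ses$hpc$time_s
  lab <- rep(NA_character_, length(tt))
  for (i in seq_len(nrow(st))) {
    lab[tt >= st$start_s[i] & tt < st$end_s[i]] <- st$state[i]
  }
  v_run <- stats::var(band[lab == "run"], na.rm = TRUE)
  v_rest <- stats::var(band[lab == "rest"], na.rm = TRUE)
  expect_lte(v_run, v_rest)
})

test_that("doubling low-gamma amplitude quadruples band power", {
  base <- sim_params(duration_s = 60, lowgamma_amp = 0.25, pink_noise_sd = 0.05,
                     run_to_rest_p = 0, rest_to_run_p = 1, ripple_rate_hz = 0,
                     line_noise_amp = 0, highgamma_amp = 0)
  dbl <- base
  dbl$lowgamma_amp <- 0.5
  s1 <- simulate_session(base, seed = 6)
  s2 <- simulate_session(dbl, seed = 6)
  p1 <- band_power(multitaper_psd(s1$hpc$voltage, rate = FS), "lowgamma")
  p2 <- band_power(multitaper_psd(s2$hpc$voltage, rate = FS), "lowgamma")
  expect_equal(p2 / p1, 4, tolerance = 0.1)
})

test_that("uncoupled sessions show no envelope-phase correlation", {
  p <- sim_params(duration_s = 60, coupling = 0, pink_noise_sd = 0.05,
                  run_to_rest_p = 0, rest_to_run_p = 1, ripple_rate_hz = 0)
  ses <- simulate_session(p, seed = 8)
  th <- analytic_signal(bandpass_zero_phase(ses$hpc, "theta"), FS)
  lg <- analytic_signal(bandpass_zero_phase(ses$hpc, "cfc_lowgamma"), FS)
  ok <- th$edge_valid & lg$edge_valid
  rc <- stats::cor(lg$envelope[ok], cos(th$phase[ok]))
  rs <- stats::cor(lg$envelope[ok], sin(th$phase[ok]))
  expect_lt(sqrt(rc^2 + rs^2), 0.05)
})

test_that("nyquist-violating ripple frequency is rejected", {
  expect_error(sim_params(ripple_freq = 600, rate_lfp = 1000), "Nyquist")
})
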