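test_that("injected ripples are recovered with accurate peak times", {
  p <- sim_params(duration_s = 120, ripple_rate_hz = 0.3,
                  run_to_rest_p = 1, rest_to_run_p = 0)
  ses <- simulate_session(p, seed = 11)
  truth <- ses$truth$ripples
  z <- zscore_by_state(ses$hpc, ses$truth$states)
  ev <- detect_ripples(z)
  expect_gt(nrow(truth), 20)
  recall <- mean(matched_within(truth$peak_s, ev$peak_s, 0.02))
  precision <- mean(matched_within(ev$peak_s, truth$peak_s, 0.02))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("noise-only rest data yields a low false-positive rate", {
  p <- sim_params(duration_s = 120, ripple_rate_hz = 0,
                  run_to_rest_p = 1, rest_to_run_p = 0)
  ses <- simulate_session(p, seed = 12)
  ev <- detect_ripples(zscore_by_state(ses$hpc, ses$truth$states))
  expect_lt(nrow(ev) / 120, 0.05)
})

test_that("events within the 200-ms refractory window are excluded", {
  # two bursts 100 ms apart on a noise background
  set.seed(13)
  fs <- FS
  n <- 30 * fs
  x <- rnorm(n, 0, 1)
  tt <- (0:(n - 1)) / fs
  burst <- function(center, amp = 8) {
    idx <- which(abs(tt - center) < 0.06)
    amp * exp(-(tt[idx] - center)^2 / (2 * 0.015^2)) *
      cos(2 * pi * 150 * (tt[idx] - center))
  }
  for (c0 in c(10, 10.1)) {
    idx <- which(abs(tt - c0) < 0.06)
    x[idx] <- x[idx] + burst(c0)
  }
  lfp <- as_lfp(x, rate = fs)
  seg <- new_segments(0, 30, "rest")
  ev <- detect_ripples(lfp, seg)
  near <- ev[ev$peak_s > 9.5 & ev$peak_s < 10.6, ]
  expect_equal(nrow(near), 1)
  expect_equal(attr(ev, "n_dropped_refractory") >= 1, TRUE)
})

test_that("accepted events always honor the spacing invariant", {
  for (s in c(31, 32)) {
    p <- sim_params(duration_s = 120, ripple_rate_hz = 0.5,
                    run_to_rest_p = 1, rest_to_run_p = 0)
    ses <- simulate_session(p, seed = s)
    ev <- detect_ripples(zscore_by_state(ses$hpc, ses$truth$states))
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_s[-1] - ev$offset_s[-nrow(ev)] > 0.2))
    }
    expect_true(all(ev$duration_ms > 30))
    expect_true(all(ev$onset_s < ev$peak_s | ev$onset_s == ev$peak_s))
    expect_true(all(ev$peak_s <= ev$offset_s))
  }
})

test_that("detection count is monotone non-increasing in the threshold", {
  p <- sim_params(duration_s = 120, ripple_rate_hz = 0.4,
                  run_to_rest_p = 1, rest_to_run_p = 0)
  ses <- simulate_session(p, seed = 33)
  z <- zscore_by_state(ses$hpc, ses$truth$states)
  counts <- vapply(c(2, 3, 4, 5), function(th) {
    nrow(detect_ripples(z, params = ripple_params(threshold_sd = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("too little rest time is refused", {
  p <- sim_params(duration_s = 8, ripple_rate_hz = 0,
                  run_to_rest_p = 1, rest_to_run_p = 0)
  ses <- simulate_session(p, seed = 34)
  expect_error(detect_ripples(zscore_by_state(ses$hpc, ses$truth$states)),
               "10 s")
})

test_that("ripple statistics are counts over analyzed time", {
  ev <- tibble::tibble(onset_s = c(1, 5, 9), offset_s = c(1.05, 5.04, 9.06),
                       peak_s = c(1.02, 5.02, 9.03),
                       amplitude_sd = c(4, 5, 6), duration_ms = c(50, 40, 60))
  seg <- new_segments(0, 30, "rest")
  st <- ripple_stats(ev, seg)
  expect_equal(st$event_rate_hz, 3 / 30)
  expect_equal(st$mean_amplitude_sd, 5)
  st0 <- ripple_stats(ev[0, ], seg)
  expect_equal(st0$event_rate_hz, 0)
  expect_true(is.na(st0$mean_amplitude_sd))
})
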