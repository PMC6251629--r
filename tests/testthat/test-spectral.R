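test_that("white-noise spectrum is flat and satisfies Parseval", {
  set.seed(5)
  x <- rnorm(120 * FS)
  psd <- multitaper_psd(x, rate = FS)
  df <- psd$freq_hz[2] - psd$freq_hz[1]
  expect_equal(sum(psd$power) * df, stats::var(x), tolerance = 0.05)
  sm <- smooth_spectrum(psd, 1)
  sel <- sm$freq_hz >= 5 & sm$freq_hz <= 100
  expect_lt(max(sm$power[sel]) / min(sm$power[sel]), 2)
})

test_that("a sinusoid concentrates its power at its frequency", {
  A <- 2
  x <- A * tone(40, 60)
  psd <- multitaper_psd(x, rate = FS)
  expect_equal(band_power(psd, c(35, 45)), A^2 / 2, tolerance = 0.1)
  pk <- peak_band_power(smooth_spectrum(psd, 1), "lowgamma")
  expect_equal(pk$peak_freq_hz, 40, tolerance = 1.5)
  expect_true(all(multitaper_psd(numeric(10 * FS), rate = FS)$power == 0))
})

test_that("multitaper PSD agrees with a plain averaged periodogram on white noise", {
  set.seed(6)
  x <- rnorm(60 * FS)
  psd <- multitaper_psd(x, rate = FS, window_s = 2)
  # independent oracle: direct FFT periodogram averaged over the same windows
  win_n <- 2 * FS
  n_win <- length(x) %/% win_n
  acc <- numeric(win_n %/% 2 + 1)
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1) * win_n + 1):(w * win_n)]
    P <- Mod(stats::fft(seg)[seq_len(win_n %/% 2 + 1)])^2 / (win_n * FS)
    acc <- acc + P
  }
  per <- acc / n_win * c(1, rep(2, win_n %/% 2 - 1), 1)
  sel <- psd$freq_hz > 2 & psd$freq_hz < 480
  ratio <- psd$power[sel] / per[sel]
  # the ratio of two unbiased estimates of a flat spectrum centers on 1
  expect_equal(mean(ratio), 1, tolerance = 0.05)
  expect_gt(stats::ks.test(log(ratio), "pnorm", mean(log(ratio)),
                           stats::sd(log(ratio)))$p.value, 0.01)
})

test_that("short bouts are analyzed whole and averaged by duration", {
  set.seed(7)
  bouts <- list(rnorm(1.4 * FS), rnorm(3 * FS), rnorm(1.1 * FS))
  psd <- multitaper_psd(bouts, rate = FS)
  expect_gt(attr(psd, "n_windows"), 2)
  expect_error(multitaper_psd(list(rnorm(0.5 * FS)), rate = FS), "at least")
})

test_that("spectrum smoothing conserves area and composes like kernels", {
  psd <- multitaper_psd(rnorm(20 * FS), rate = FS)
  flat <- psd
  flat$power <- rep(2, nrow(flat))
  attributes(flat) <- attributes(psd)
  expect_equal(smooth_spectrum(flat, 2)$power, rep(2, nrow(flat)))

  # delta-like interior peak: area preserved within 1%
  delta <- psd
  delta$power <- rep(0, nrow(delta))
  delta$power[200] <- 10
  attributes(delta) <- attributes(psd)
  sm <- smooth_spectrum(delta, 2)
  expect_equal(sum(sm$power), 10, tolerance = 0.01)

  # smoothing twice with a box == once with the triangular composite
  w <- 5
  sm2 <- smooth_spectrum(smooth_spectrum(delta, w * 0.5), w * 0.5)
  df <- delta$freq_hz[2] - delta$freq_hz[1]
  kern <- rep(1 / w, w)
  tri <- stats::convolve(kern, rev(kern), type = "open")
  idx <- 200 + seq_along(tri) - w
  expect_equal(sm2$power[idx], 10 * tri, tolerance = 1e-9)
})

test_that("peak band power matches a brute-force scan", {
  psd <- multitaper_psd(rnorm(20 * FS), rate = FS)
  pk <- peak_band_power(psd, "lowgamma")
  sel <- which(psd$freq_hz >= 30 & psd$freq_hz <= 60)
  i <- sel[which.max(psd$power[sel])]
  expect_equal(pk$peak_power, psd$power[i])
  expect_equal(pk$peak_freq_hz, psd$freq_hz[i])

  # monotone spectrum: peak at the band's lower edge
  mono <- psd
  mono$power <- rev(sort(psd$power))
  attributes(mono) <- attributes(psd)
  expect_equal(peak_band_power(mono, c(30, 60))$peak_freq_hz, 30)
  expect_error(peak_band_power(psd, c(600, 700)), "outside")
})

test_that("spectrogram has the expected geometry and follows a chirp", {
  expect_error(spectrogram(rnorm(5 * FS), rate = FS, window_s = 1, step_s = 2),
               "exceed")
  sg0 <- spectrogram(numeric(5 * FS), rate = FS, window_s = 1, step_s = 0.5)
  expect_true(all(sg0$power == 0))
  expect_equal(length(unique(sg0$time_s)), floor((5 - 1) / 0.5) + 1)

  # linear chirp 10 -> 90 Hz over 20 s
  tt <- (0:(20 * FS - 1)) / FS
  chirp <- sin(2 * pi * (10 * tt + 2 * tt^2))
  sg <- spectrogram(chirp, rate = FS, window_s = 1, step_s = 1)
  ridge <- dplyr::summarise(dplyr::group_by(sg, time_s),
                            f = freq_hz[which.max(power)])
  expect_true(all(abs(ridge$f - (10 + 4 * ridge$time_s)) < 3))
})

test_that("low-gamma gain between paired sessions is recovered as squared power", {
  base <- sim_params(duration_s = 60, run_to_rest_p = 0, rest_to_run_p = 1,
                     ripple_rate_hz = 0, pink_noise_sd = 0.05,
                     line_noise_amp = 0, highgamma_amp = 0)
  hi <- base
  hi$condition_gain <- 1.5
  s1 <- simulate_session(base, seed = 10)
  s2 <- simulate_session(hi, seed = 10)
  r <- band_power(multitaper_psd(s2$hpc$voltage, rate = FS), "lowgamma") /
    band_power(multitaper_psd(s1$hpc$voltage, rate = FS), "lowgamma")
  expect_equal(r, 1.5^2, tolerance = 0.15)
})

test_that("slepian tapers match the reference implementation", {
  tp <- lfpkit:::dpss_tapers(64, 3, 5)
  expect_equal(dim(tp), c(64, 5))
  expect_equal(colSums(tp^2), rep(1, 5), tolerance = 1e-12)
  # orthonormality
  g <- crossprod(tp)
  expect_equal(g, diag(5), tolerance = 1e-9, ignore_attr = TRUE)
  # frozen oracle values (scipy.signal.windows.dpss(64, 3, 5))
  expect_equal(tp[c(1, 16, 32, 49, 64), 1],
               c(0.000356444210234, 0.067352467611874, 0.229704010511753,
                 0.067352467611875, 0.000356444210234), tolerance = 1e-10)
  s2 <- if (tp[6, 2] < 0) -tp[, 2] else tp[, 2]
  expect_equal(s2[c(6, 21, 41)],
               c(0.025245021500827, 0.199386637018301, -0.189070830059479),
               tolerance = 1e-10)
})
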