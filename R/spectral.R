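# Multitaper spectral power estimation.
#
# A 5-taper DPSS estimate (time-bandwidth NW = (K+1)/2 = 3) over 2-s
# windows with 50% overlap is the default; behavioral bouts shorter than
# one window but at least 1 s long are analyzed whole with tapers re-fit
# to their length (lengths quantized to 0.25-s steps so taper sets can
# be cached), and their spectra interpolated onto the reference grid.
# Spectra are one-sided and normalized so that the integral over
# [0, Nyquist] equals the signal variance.

mt_psd_one <- function(x, rate, n_tapers) {
  n <- length(x)
  nw <- (n_tapers + 1) / 2
  tp <- dpss_tapers(n, nw, n_tapers)
  nf <- n %/% 2 + 1
  acc <- numeric(nf)
  for (k in seq_len(n_tapers)) {
    X <- stats::fft(tp[, k] * x)
    acc <- acc + (Mod(X[seq_len(nf)])^2) / rate
  }
  p <- acc / n_tapers
  # One-sided: double all bins except DC (and Nyquist when n is even).
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(freq_hz = (seq_len(nf) - 1) * rate / n, power = p * dbl)
}

# Collect analysis windows (numeric vectors) from segments.
collect_windows <- function(segs, rate, window_s, overlap, min_segment_s,
                            quantum_s = 0.25) {
  win_n <- as.integer(round(window_s * rate))
  step_n <- max(1L, as.integer(round(win_n * (1 - overlap))))
  min_n <- as.integer(round(min_segment_s * rate))
  q_n <- as.integer(round(quantum_s * rate))
  out <- list()
  for (seg in segs) {
    len <- length(seg)
    if (len >= win_n) {
      starts <- seq.int(1L, len - win_n + 1L, by = step_n)
      for (s in starts) out[[length(out) + 1L]] <- seg[s:(s + win_n - 1L)]
    } else {
      keep_n <- (len %/% q_n) * q_n
      if (keep_n >= min_n) out[[length(out) + 1L]] <- seg[seq_len(keep_n)]
    }
  }
  out
}

#' Multitaper power spectral density
#'
#' Averages DPSS-tapered periodograms over tapers and windows,
#' duration-weighted across variable-length behavioral bouts.
#'
#' @param x A numeric vector (one segment), a list of numeric vectors
#'   (one per bout), or a `state_lfp` tibble from [zscore_by_state()]
#'   together with `state`.
#' @param rate Sampling rate in Hz (taken from a `state_lfp` input).
#' @param state For `state_lfp` input, which state to analyze
#'   (`"run"`/`"rest"`).
#' @param n_tapers Number of DPSS tapers (default 5; time-bandwidth
#'   `NW = (n_tapers + 1) / 2`).
#' @param window_s Analysis window length in seconds.
#' @param overlap Fractional overlap of consecutive windows within a bout.
#' @param min_segment_s Shortest bout analyzed (whole, tapers re-fit).
#' @return A tibble of class `psd_tbl` with columns `freq_hz`, `power`
#'   and attributes `n_tapers`, `time_bandwidth`, `n_windows`, `rate`.
#' @examples
#' x <- sin(2 * pi * 40 * seq(0, 10, by = 1e-3))
#' psd <- multitaper_psd(x, rate = 1000)
#' peak_band_power(psd, "lowgamma")
#' @export
multitaper_psd <- function(x, rate = NULL, state = NULL, n_tapers = 5,
                           window_s = 2, overlap = 0.5, min_segment_s = 1) {
  if (inherits(x, "state_lfp")) {
    rate <- rate %||% lfp_rate(x)
    if (is.null(state)) stop("state is required for state_lfp input", call. = FALSE)
    segs <- state_bouts(x, state)
  } else if (is.list(x) && !is.data.frame(x)) {
    segs <- lapply(x, as.numeric)
  } else {
    segs <- list(as.numeric(x))
  }
  if (is.null(rate)) stop("rate is required", call. = FALSE)
  wins <- collect_windows(segs, rate, window_s, overlap, min_segment_s)
  if (length(wins) == 0) {
    stop(sprintf("no segment is at least %g s long", min_segment_s),
         call. = FALSE)
  }
  win_n <- as.integer(round(window_s * rate))
  ref_n <- max(vapply(wins, length, integer(1)), win_n)
  ref_f <- (seq_len(ref_n %/% 2 + 1) - 1) * rate / ref_n
  acc <- numeric(length(ref_f))
  wsum <- 0
  for (w in wins) {
    est <- mt_psd_one(w, rate, n_tapers)
    p <- if (length(est$freq_hz) == length(ref_f)) est$power
         else stats::approx(est$freq_hz, est$power, xout = ref_f, rule = 2)$y
    wt <- length(w)
    acc <- acc + wt * p
    wsum <- wsum + wt
  }
  out <- tibble::tibble(freq_hz = ref_f, power = acc / wsum)
  structure(out, class = c("psd_tbl", class(out)),
            n_tapers = n_tapers, time_bandwidth = (n_tapers + 1) / 2,
            n_windows = length(wins), rate = rate)
}

#' Smooth a power spectrum
#'
#' Moving average over a `bw_hz` bandwidth (truncated, renormalized at
#' the grid edges); integrated power is conserved away from the edges.
#'
#' @param psd A `psd_tbl` from [multitaper_psd()].
#' @param bw_hz Smoothing bandwidth in Hz (default 1).
#' @return A smoothed `psd_tbl`.
#' @export
smooth_spectrum <- function(psd, bw_hz = 1) {
  df <- psd$freq_hz[2] - psd$freq_hz[1]
  if (bw_hz < df) stop("bw_hz must be at least the grid spacing", call. = FALSE)
  w <- as.integer(round(bw_hz / df))
  if (w %% 2 == 0) w <- w + 1L
  out <- psd
  out$power <- moving_average(psd$power, w)
  attributes(out) <- attributes(psd)
  out
}

#' Peak power within a frequency band
#'
#' The maximum (smoothed) spectral value inside `[low, high]` and the
#' frequency at which it occurs; ties resolve to the lowest frequency.
#'
#' @param psd A `psd_tbl`.
#' @param band Band name or `c(low, high)` in Hz.
#' @return One-row tibble: `band`, `peak_power`, `peak_freq_hz`.
#' @export
peak_band_power <- function(psd, band) {
  bd <- band_def(band)
  sel <- psd$freq_hz >= bd$low_hz & psd$freq_hz <= bd$high_hz
  if (!any(sel)) {
    stop(sprintf("band %g-%g Hz outside the spectrum grid", bd$low_hz, bd$high_hz),
         call. = FALSE)
  }
  p <- psd$power[sel]
  f <- psd$freq_hz[sel]
  i <- which.max(p)
  tibble::tibble(band = bd$band, peak_power = p[i], peak_freq_hz = f[i])
}

#' Band-integrated power
#'
#' Integral of the spectrum over a band (sum of in-band bins times the
#' grid spacing); reported alongside the peak as a robustness check.
#'
#' @inheritParams peak_band_power
#' @return Integrated power (scalar).
#' @export
band_power <- function(psd, band) {
  bd <- band_def(band)
  sel <- psd$freq_hz >= bd$low_hz & psd$freq_hz <= bd$high_hz
  if (!any(sel)) {
    stop(sprintf("band %g-%g Hz outside the spectrum grid", bd$low_hz, bd$high_hz),
         call. = FALSE)
  }
  df <- psd$freq_hz[2] - psd$freq_hz[1]
  sum(psd$power[sel]) * df
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power for time-frequency figures.
#'
#' @param x Numeric vector or lfp tibble.
#' @param rate Sampling rate; taken from `x` when omitted.
#' @param window_s Window length (s).
#' @param step_s Step between window starts (s); must not exceed
#'   `window_s`.
#' @param n_tapers Number of DPSS tapers.
#' @return A tibble of class `spectrogram_tbl` with columns `time_s`
#'   (window center), `freq_hz`, `power`.
#' @export
spectrogram <- function(x, rate = NULL, window_s = 1, step_s = 0.5,
                        n_tapers = 5) {
  if (is.data.frame(x)) {
    rate <- rate %||% lfp_rate(x)
    x <- x$voltage
  }
  if (step_s > window_s) stop("step_s must not exceed window_s", call. = FALSE)
  x <- as.numeric(x)
  win_n <- as.integer(round(window_s * rate))
  step_n <- as.integer(round(step_s * rate))
  if (length(x) < win_n) stop("signal shorter than one window", call. = FALSE)
  starts <- seq.int(1L, length(x) - win_n + 1L, by = step_n)
  cols <- purrr::map_dfr(starts, function(s) {
    est <- mt_psd_one(x[s:(s + win_n - 1L)], rate, n_tapers)
    tibble::tibble(time_s = (s - 1 + win_n / 2) / rate,
                   freq_hz = est$freq_hz, power = est$power)
  })
  structure(cols, class = c("spectrogram_tbl", class(cols)), rate = rate)
}
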