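# Shared fixtures, generated in code at test time.

FS <- 1000

# A pure tone at frequency f (Hz), duration in seconds.
tone <- function(f, duration_s = 10, amp = 1, fs = FS, phase = 0) {
  amp * cos(2 * pi * f * (0:(duration_s * fs - 1)) / fs + phase)
}

# Index range away from filter/Hilbert edge effects.
interior <- function(x, margin_s = 2, fs = FS) {
  n <- length(x)
  m <- round(margin_s * fs)
  seq.int(m + 1, n - m)
}

# Simulation parameters for a session that is entirely one state.
pure_state_params <- function(state = c("rest", "run"), duration_s = 120, ...) {
  state <- match.arg(state)
  if (state == "rest") {
    sim_params(duration_s = duration_s, run_to_rest_p = 1, rest_to_run_p = 0, ...)
  } else {
    sim_params(duration_s = duration_s, run_to_rest_p = 0, rest_to_run_p = 1, ...)
  }
}

# Straight-line position trace at constant speed (cm/s), 30 Hz.
line_position <- function(speed_cm_s, duration_s = 60, rate = 30) {
  tt <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  tibble::tibble(time_s = tt, x_cm = speed_cm_s * tt, y_cm = 0)
}

# Analytic-binning oracle for an envelope of the form a + b*cos(phi - mu):
# exact mean amplitude per phase bin, then the entropy-based index.
mi_oracle_cosine <- function(a, b, mu, n_bins = 18) {
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  m <- a + b * (sin(edges[-1] - mu) - sin(edges[-(n_bins + 1)] - mu)) /
    (2 * pi / n_bins)
  p <- m / sum(m)
  h <- -sum(p * log(p))
  (log(n_bins) - h) / log(n_bins)
}

# Match each event time to its nearest reference; TRUE if within tol_s.
matched_within <- function(times, reference, tol_s) {
  if (length(times) == 0) return(logical(0))
  vapply(times, function(tp) min(abs(reference - tp)) <= tol_s, logical(1))
}
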