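# Ground-truthed synthetic two-channel LFP + position sessions.
#
# The generator emulates the statistical structure the analysis pipeline
# assumes: a two-state (run/rest) locomotion chain, state-gated theta,
# low-gamma whose instantaneous amplitude is modulated by theta phase,
# high-gamma, rest-only Poisson ripple bursts, 60/180 Hz line noise, a
# 1/f background, and a lagged shared low-gamma component on the second
# (prefrontal) channel. Every latent quantity is returned as ground
# truth so each pipeline stage can be scored without animal data.

#' Simulation parameters
#'
#' Builds the parameter list for [simulate_session()]. Defaults describe a
#' plausible mouse open-field session: theta at 7 Hz (stronger during
#' running), phase-coupled low-gamma at 42 Hz, high-gamma at 80 Hz,
#' rest-only ripples at 150 Hz occurring at 0.3 Hz, 60/180 Hz mains
#' contamination and a 1/f background.
#'
#' @param duration_s Session length in seconds.
#' @param theta_freq,theta_amp_run,theta_amp_rest Theta frequency (Hz) and
#'   state-dependent amplitudes (a.u.).
#' @param lowgamma_freq,lowgamma_amp Low-gamma carrier frequency and base
#'   amplitude.
#' @param coupling Depth kappa in `[0, 1]` of the theta-phase modulation of
#'   low-gamma amplitude: the instantaneous amplitude is
#'   `lowgamma_amp * gain * (1 - kappa/2 + kappa/2 * cos(phase - preferred_phase))`.
#' @param preferred_phase Theta phase (radians, `[0, 2*pi)`) at which
#'   low-gamma amplitude is greatest.
#' @param highgamma_freq,highgamma_amp High-gamma carrier and run-state
#'   amplitude (halved during rest).
#' @param ripple_rate_hz Poisson rate of ripple events during rest.
#' @param ripple_freq,ripple_dur_ms Ripple carrier frequency and nominal
#'   burst duration.
#' @param ripple_amp_sd Ripple envelope peak, in units of the rest-state
#'   ripple-band background SD, so detector operating points are
#'   controllable.
#' @param line_noise_amp Amplitude of the 60 Hz line component (the 180 Hz
#'   harmonic is generated at half this amplitude).
#' @param pink_noise_sd SD of the 1/f background.
#' @param condition_gain Multiplier on low-gamma amplitude, modelling a
#'   chemogenetic treatment effect.
#' @param interareal_lag_ms Delay of the shared low-gamma component on the
#'   prefrontal channel.
#' @param run_to_rest_p,rest_to_run_p Per-step (at the position rate) exit
#'   probabilities of the locomotion chain once the 2-s minimum dwell has
#'   elapsed.
#' @param run_speed_cm_s,rest_speed_cm_s Locomotion speeds of the two
#'   states; rest must stay below the 0.5 cm/s rest threshold.
#' @param rate_lfp,rate_pos LFP and position sampling rates (Hz).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(duration_s = 600,
                       theta_freq = 7, theta_amp_run = 1, theta_amp_rest = 0.3,
                       lowgamma_freq = 42, lowgamma_amp = 0.25,
                       coupling = 0.8, preferred_phase = pi / 2,
                       highgamma_freq = 80, highgamma_amp = 0.1,
                       ripple_rate_hz = 0.3, ripple_freq = 150,
                       ripple_dur_ms = 60, ripple_amp_sd = 6,
                       line_noise_amp = 0.05, pink_noise_sd = 0.5,
                       condition_gain = 1, interareal_lag_ms = 5,
                       run_to_rest_p = 1 / (15 * 30),
                       rest_to_run_p = 1 / (12 * 30),
                       run_speed_cm_s = 10, rest_speed_cm_s = 0.2,
                       rate_lfp = 1000, rate_pos = 30) {
  p <- as.list(environment())
  amps <- c(p$theta_amp_run, p$theta_amp_rest, p$lowgamma_amp, p$highgamma_amp,
            p$line_noise_amp, p$pink_noise_sd, p$ripple_amp_sd, p$condition_gain)
  if (any(amps < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (p$coupling < 0 || p$coupling > 1) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  if (p$duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (p$ripple_freq >= p$rate_lfp / 2) {
    stop(sprintf("ripple_freq %g Hz is at or above Nyquist for rate %g Hz",
                 p$ripple_freq, p$rate_lfp), call. = FALSE)
  }
  p$preferred_phase <- wrap_2pi(p$preferred_phase)
  structure(p, class = "sim_params")
}

#' Simulate a locomotion trace
#'
#' Generates a two-state (run/rest) Markov chain at the position sampling
#' rate with a 2-s minimum dwell per bout, then a 2-D trajectory inside an
#' 80 x 80 cm arena: during run bouts the animal moves at
#' `run_speed_cm_s` along a smoothly wandering heading; during rest it
#' jitters at `rest_speed_cm_s` (< 0.5 cm/s).
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with `position` (tibble `time_s`, `x_cm`, `y_cm`) and
#'   `states` (ground-truth [new_segments()] tibble tiling
#'   `[0, duration_s)`).
#' @export
simulate_position <- function(params, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    fs <- params$rate_pos
    n <- as.integer(round(params$duration_s * fs))
    min_dwell <- as.integer(2 * fs)
    exit_p <- c(run = params$run_to_rest_p, rest = params$rest_to_run_p)
    state <- character(0)
    # Initial state from the chain's stationary distribution; a zero
    # entry probability makes the other state absorbing.
    p_run <- if (sum(exit_p) > 0) exit_p[["rest"]] / sum(exit_p) else 0.5
    cur <- if (stats::runif(1) < p_run) "run" else "rest"
    while (length(state) < n) {
      dwell <- if (exit_p[[cur]] <= 0) n
               else min_dwell + stats::rgeom(1, exit_p[[cur]])
      state <- c(state, rep(cur, dwell))
      cur <- if (cur == "run") "rest" else "run"
    }
    state <- state[seq_len(n)]

    # Trajectory: constant-speed travel along a smoothly wandering
    # heading that steers away from the arena walls (80 x 80 cm) before
    # reaching them, so measured speed never collapses at a boundary.
    dturn <- stats::rnorm(n, 0, 0.05)
    jitter_dir <- stats::runif(n, 0, 2 * pi)
    x <- y <- numeric(n)
    x[1] <- 40; y[1] <- 40
    heading <- stats::runif(1, 0, 2 * pi)
    max_turn <- 3 / fs  # steering rate 3 rad/s, gentle on measured speed
    for (i in 2:n) {
      if (state[i] == "run") {
        heading <- heading + dturn[i]
        margin <- 15
        if (x[i - 1] < margin || x[i - 1] > 80 - margin ||
            y[i - 1] < margin || y[i - 1] > 80 - margin) {
          to_center <- atan2(40 - y[i - 1], 40 - x[i - 1])
          dh <- atan2(sin(to_center - heading), cos(to_center - heading))
          heading <- heading + sign(dh) * min(abs(dh), max_turn)
        }
        stp <- params$run_speed_cm_s / fs
        x[i] <- x[i - 1] + stp * cos(heading)
        y[i] <- y[i - 1] + stp * sin(heading)
      } else {
        stp <- params$rest_speed_cm_s / fs
        x[i] <- x[i - 1] + stp * cos(jitter_dir[i])
        y[i] <- y[i - 1] + stp * sin(jitter_dir[i])
      }
      x[i] <- min(max(x[i], 0.5), 79.5)
      y[i] <- min(max(y[i], 0.5), 79.5)
    }

    rr <- rle(state)
    ends <- cumsum(rr$lengths)
    starts <- c(0L, ends[-length(ends)])
    list(
      position = tibble::tibble(time_s = (seq_len(n) - 1) / fs,
                                x_cm = x, y_cm = y),
      states = new_segments(starts / fs, ends / fs, rr$values)
    )
  })
}

# 1/f ("pink") background: white Gaussian noise spectrally shaped with a
# 1/sqrt(f) amplitude profile floored at 1 Hz, rescaled to target SD.
pink_noise <- function(n, fs, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)            # two-sided frequency magnitudes
  shape <- 1 / sqrt(pmax(f, 1))   # flat below 1 Hz
  shape[1] <- 0                   # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x * sd_target / stats::sd(x)
}

# Smooth 0/1 gate for state intervals with a cosine ramp (default 100 ms)
# so state-gated components do not click at boundaries.
state_gate <- function(t, states, label, ramp_s = 0.1) {
  g <- numeric(length(t))
  for (i in which(states$state == label)) {
    g <- pmax(g, pmin(1, pmin((t - states$start_s[i]) / ramp_s,
                              (states$end_s[i] - t) / ramp_s)))
  }
  pmax(g, 0)
}

#' Simulate a two-channel LFP session from a state sequence
#'
#' Builds the hippocampal trace as 1/f background + state-gated theta +
#' theta-phase-modulated low-gamma + state-gated high-gamma + rest-only
#' Gaussian-windowed ripple bursts + 60/180 Hz line noise. The prefrontal
#' trace shares the low-gamma component delayed by `interareal_lag_ms`
#' over independent background noise. Theta phase is taken analytically
#' from the generating oscillator, so the coupling ground truth is exact.
#'
#' @param params A [sim_params()] list.
#' @param states Ground-truth state segments tiling the session (from
#'   [simulate_position()]).
#' @param seed Integer seed for the noise and event streams.
#' @return A list with `hpc` and `pfc` ([as_lfp()] tibbles) and `truth`,
#'   a list holding `states`, `ripples` (tibble `onset_s`, `peak_s`,
#'   `offset_s`), `theta_phase`, `lowgamma_envelope`, `coupling`,
#'   `preferred_phase`, `condition_gain`, `lag_ms`.
#' @export
simulate_lfp <- function(params, states, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  total <- max(states$end_s)
  if (abs(total - params$duration_s) > 1 / params$rate_pos + 1e-9) {
    stop("state intervals must tile [0, duration_s)", call. = FALSE)
  }
  with_seed(seed, {
    fs <- params$rate_lfp
    n <- as.integer(round(params$duration_s * fs))
    t <- (seq_len(n) - 1) / fs

    gate_run <- state_gate(t, states, "run")
    gate_rest <- state_gate(t, states, "rest")

    phi0 <- stats::runif(1, 0, 2 * pi)
    theta_phase <- wrap_2pi(2 * pi * params$theta_freq * t + phi0)
    theta_amp <- params$theta_amp_rest +
      (params$theta_amp_run - params$theta_amp_rest) * gate_run
    theta <- theta_amp * cos(theta_phase)

    k <- params$coupling
    lg_env <- params$lowgamma_amp * params$condition_gain *
      (1 - k / 2 + (k / 2) * cos(theta_phase - params$preferred_phase))
    psi_lg <- stats::runif(1, 0, 2 * pi)
    lowgamma <- lg_env * cos(2 * pi * params$lowgamma_freq * t + psi_lg)

    psi_hg <- stats::runif(1, 0, 2 * pi)
    hg_amp <- params$highgamma_amp * (0.5 + 0.5 * gate_run)
    highgamma <- hg_amp * cos(2 * pi * params$highgamma_freq * t + psi_hg)

    line <- params$line_noise_amp * (sin(2 * pi * 60 * t) +
                                       0.5 * sin(2 * pi * 180 * t))
    bg_hpc <- pink_noise(n, fs, params$pink_noise_sd)
    background <- bg_hpc + theta + lowgamma + highgamma + line

    # Ripple bursts: Poisson onsets inside rest intervals, kept 200 ms
    # clear of interval edges and of each other; amplitude expressed in
    # units of the rest-state ripple-band background SD.
    ripples <- make_ripple_truth(params, states)
    ripple_sig <- numeric(n)
    if (nrow(ripples) > 0) {
      rest_idx <- unlist(lapply(which(states$state == "rest"), function(i) {
        interval_indices(states$start_s[i], states$end_s[i], fs, n)
      }))
      sd_bg <- stats::sd(fir_bandpass(background, fs,
                                      low = 100, high = 300)[rest_idx])
      amp <- params$ripple_amp_sd * sd_bg
      half_win <- params$ripple_dur_ms / 1000 / 2
      sigma <- params$ripple_dur_ms / 1000 / 4
      for (i in seq_len(nrow(ripples))) {
        ctr <- ripples$peak_s[i]
        idx <- interval_indices(ctr - 2 * half_win, ctr + 2 * half_win, fs, n)
        tt <- t[idx] - ctr
        ripple_sig[idx] <- ripple_sig[idx] +
          amp * exp(-tt^2 / (2 * sigma^2)) *
          cos(2 * pi * params$ripple_freq * tt)
      }
    }

    hpc <- background + ripple_sig

    lag_n <- as.integer(round(params$interareal_lag_ms / 1000 * fs))
    lg_shift <- c(rep(0, lag_n), lowgamma)[seq_len(n)]
    bg_pfc <- pink_noise(n, fs, params$pink_noise_sd)
    pfc <- bg_pfc + lg_shift + line

    list(
      hpc = as_lfp(hpc, rate = fs, role = "hpc"),
      pfc = as_lfp(pfc, rate = fs, role = "pfc"),
      truth = list(
        states = states,
        ripples = ripples,
        theta_phase = theta_phase,
        lowgamma_envelope = lg_env,
        coupling = params$coupling,
        preferred_phase = params$preferred_phase,
        condition_gain = params$condition_gain,
        lag_ms = params$interareal_lag_ms
      )
    )
  })
}

# Draw ripple onset times: per rest interval, a hard-core renewal
# process -- a 260-ms dead time (burst + refractory spacing) followed by
# an exponential gap whose rate is compensated so the realized mean
# event rate equals ripple_rate_hz. Onsets keep a 200-ms margin from
# interval edges (ripples occur mid-immobility).
make_ripple_truth <- function(params, states, margin_s = 0.2) {
  dur <- params$ripple_dur_ms / 1000
  onsets <- numeric(0)
  if (params$ripple_rate_hz > 0) {
    dead <- dur + margin_s
    if (params$ripple_rate_hz * dead >= 0.9) {
      stop("ripple_rate_hz too high for the 200-ms inter-event spacing",
           call. = FALSE)
    }
    rate_adj <- params$ripple_rate_hz / (1 - params$ripple_rate_hz * dead)
    for (i in which(states$state == "rest")) {
      lo <- states$start_s[i] + margin_s
      hi <- states$end_s[i] - margin_s - dur
      if (hi <= lo) next
      pos <- lo + stats::rexp(1, rate_adj)
      while (pos < hi) {
        onsets <- c(onsets, pos)
        pos <- pos + dead + stats::rexp(1, rate_adj)
      }
    }
  }
  onsets <- sort(onsets)
  tibble::tibble(onset_s = onsets,
                 peak_s = onsets + dur / 2,
                 offset_s = onsets + dur)
}

#' Simulate a complete ground-truthed session
#'
#' Convenience wrapper chaining [simulate_position()] and
#' [simulate_lfp()]. The position/state stream and the LFP noise stream
#' use seeds derived from `seed` (`seed` and `seed + 1e5`), so condition
#' pairs can share behavior while drawing independent noise.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer base seed.
#' @param state_seed Optional explicit seed for the locomotion chain
#'   (defaults to `seed`); lets paired sessions share identical behavior.
#' @return A list of class `lfp_session`: `hpc`, `pfc`, `position`,
#'   `truth`, `params`, `seed`.
#' @examples
#' ses <- simulate_session(sim_params(duration_s = 60), seed = 1)
#' ses$truth$states
#' @export
simulate_session <- function(params, seed = 1, state_seed = seed) {
  pos <- simulate_position(params, seed = state_seed)
  sig <- simulate_lfp(params, pos$states, seed = seed + 100000L)
  structure(list(hpc = sig$hpc, pfc = sig$pfc, position = pos$position,
                 truth = c(sig$truth, list(position = pos$position)),
                 params = params, seed = seed),
            class = "lfp_session")
}

#' Simulate a paired vehicle/treatment session
#'
#' Generates two sessions sharing the same locomotion chain (same state
#' seed) but independent noise, differing only in the low-gamma gain and
#' ripple rate -- the within-animal design of a chemogenetic experiment.
#' `gain > 1` with `ripple_rate_mult < 1` emulates CA2 activation
#' (excitatory DREADD: more low-gamma, fewer ripples); `gain < 1` with
#' `ripple_rate_mult > 1` emulates CA2 silencing.
#'
#' @param params Baseline [sim_params()] (used as the vehicle condition).
#' @param seed Integer seed.
#' @param gain Low-gamma amplitude multiplier for the treated session.
#' @param ripple_rate_mult Ripple-rate multiplier for the treated session.
#' @return A list with elements `vehicle` and `cno`, each an
#'   `lfp_session`.
#' @export
simulate_condition_pair <- function(params, seed = 1, gain = 1.5,
                                    ripple_rate_mult = 0.5) {
  treated <- params
  treated$condition_gain <- params$condition_gain * gain
  treated$ripple_rate_hz <- params$ripple_rate_hz * ripple_rate_mult
  list(
    vehicle = simulate_session(params, seed = seed, state_seed = seed),
    cno = simulate_session(treated, seed = seed + 7919L, state_seed = seed)
  )
}
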