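# Broom-style tidiers and print methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a modulation result
#'
#' @param x A `modulation_result` from [modulation_index()].
#' @param ... Unused.
#' @return The phase-bin amplitude distribution: `phase_bin_rad`,
#'   `amplitude`, `p`.
#' @export
tidy.modulation_result <- function(x, ...) x$bins

#' @rdname tidy.modulation_result
#' @return `glance()`: one row with `mi`, `preferred_phase_rad`,
#'   `n_bins`, `n_samples`, `n_empty_bins`.
#' @export
glance.modulation_result <- function(x, ...) {
  tibble::tibble(mi = x$mi, preferred_phase_rad = x$preferred_phase_rad,
                 n_bins = x$n_bins, n_samples = x$n_samples,
                 n_empty_bins = x$n_empty_bins)
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf(
    "Theta-gamma modulation: MI = %.4g, preferred phase = %.1f deg (n = %d)\n",
    x$mi, x$preferred_phase_rad * 180 / pi, x$n_samples))
  invisible(x)
}

#' Tidy a phase-lag result
#'
#' @param x A `phase_lag_result` from [phase_lag()].
#' @param ... Unused.
#' @return One row per v-test target (`0`, `2pi`) with the test
#'   statistics.
#' @export
tidy.phase_lag_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$v_zero, target = "0", .before = 1),
    dplyr::mutate(x$v_2pi, target = "2pi", .before = 1))
}

#' @rdname tidy.phase_lag_result
#' @export
glance.phase_lag_result <- function(x, ...) {
  tibble::tibble(mean_phase_diff_rad = x$mean_phase_diff_rad,
                 resultant_length = x$resultant_length,
                 p_vs_zero = x$v_zero$p, p_vs_2pi = x$v_2pi$p, n = x$n)
}

#' @export
print.phase_lag_result <- function(x, ...) {
  cat(sprintf(
    "Phase lag (%s): mean diff = %.3f rad, R = %.3f, p(vs 0) = %.3g, n = %d\n",
    x$band, x$mean_phase_diff_rad, x$resultant_length, x$v_zero$p, x$n))
  invisible(x)
}

#' Tidy a session result
#'
#' @param x A `session_result` from [analyze_session()].
#' @param ... Unused.
#' @return A long tibble with columns `metric`, `value`.
#' @export
tidy.session_result <- function(x, ...) {
  g <- glance(x)
  tidyr::pivot_longer(g, dplyr::where(is.numeric),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.session_result
#' @return `glance()`: one row with the headline scalars (per-state peak
#'   band powers, MI, band coherence, ripple rate/amplitude, locomotion
#'   summary). Metrics whose stage did not run are `NA`.
#' @export
glance.session_result <- function(x, ...) {
  out <- tibble::tibble(session_id = x$session_id, treatment = x$treatment)
  if (nrow(x$power) > 0) {
    for (i in seq_len(nrow(x$power))) {
      out[[paste0(x$power$state[i], "_", x$power$band[i], "_peak_power")]] <-
        x$power$peak_power[i]
    }
  }
  out$mi <- if (!is.null(x$cfc)) x$cfc$mi else NA_real_
  out$preferred_phase_rad <-
    if (!is.null(x$cfc)) x$cfc$preferred_phase_rad else NA_real_
  if (!is.null(x$synchrony)) {
    out$lowgamma_coherence <- x$synchrony$band_coherence
    out$phase_lag_rad <- x$synchrony$phase_lag$mean_phase_diff_rad
  }
  if (!is.null(x$ripples)) {
    out$ripple_rate_hz <- x$ripples$stats$event_rate_hz
    out$ripple_amplitude_sd <- x$ripples$stats$mean_amplitude_sd
  }
  out$percent_time_running <- x$locomotion$percent_time_running
  out$mean_run_speed_cm_s <- x$locomotion$mean_run_speed_cm_s
  out
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("Session result%s (window %.0f-%.0f s)\n",
              if (is.na(x$session_id)) "" else paste0(" ", x$session_id),
              x$window[1], x$window[2]))
  cat(sprintf("  run %.1f s, rest %.1f s, %.1f%% time running\n",
              x$locomotion$run_time_s, x$locomotion$rest_time_s,
              x$locomotion$percent_time_running))
  if (nrow(x$power) > 0) {
    p <- x$power
    cat("  peak powers (a.u.):\n")
    for (i in seq_len(nrow(p))) {
      cat(sprintf("    %-4s %-10s %.4g at %.1f Hz\n", p$state[i], p$band[i],
                  p$peak_power[i], p$peak_freq_hz[i]))
    }
  }
  if (!is.null(x$cfc)) {
    cat(sprintf("  coupling: MI = %.4g, preferred phase = %.1f deg\n",
                x$cfc$mi, x$cfc$preferred_phase_rad * 180 / pi))
  }
  if (!is.null(x$synchrony)) {
    cat(sprintf("  low-gamma coherence = %.3f, phase lag = %.3f rad\n",
                x$synchrony$band_coherence,
                x$synchrony$phase_lag$mean_phase_diff_rad))
  }
  if (!is.null(x$ripples)) {
    s <- x$ripples$stats
    cat(sprintf("  ripples: %.3f Hz (%d events in %.1f s), mean amplitude %.2f SD\n",
                s$event_rate_hz, s$n_events, s$analyzed_time_s,
                s$mean_amplitude_sd))
  }
  if (length(x$missing) > 0) {
    cat("  missing:", paste(x$missing, collapse = "; "), "\n")
  }
  invisible(x)
}
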