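# ggplot2 figure methods. Figures are report side effects, never inputs
# to metrics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object A `psd_tbl` from [multitaper_psd()].
#' @param ... Unused.
#' @export
autoplot.psd_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a coherence spectrum
#'
#' @param object A `coherence_tbl` from [coherence_spectrum()].
#' @param ... Unused.
#' @export
autoplot.coherence_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence") +
    ggplot2::theme_minimal()
}

#' Plot a multitaper spectrogram
#'
#' @param object A `spectrogram_tbl` from [spectrogram()].
#' @param max_freq_hz Upper frequency limit shown.
#' @param ... Unused.
#' @export
autoplot.spectrogram_tbl <- function(object, max_freq_hz = 100, ...) {
  dat <- object[object$freq_hz <= max_freq_hz, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                    fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the theta-phase amplitude distribution
#'
#' @param object A `modulation_result` from [modulation_index()].
#' @param ... Unused.
#' @export
autoplot.modulation_result <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$phase_bin_rad * 180 / pi,
                               y = .data$p)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Theta phase (deg)", y = "Normalized gamma amplitude",
                  subtitle = sprintf("MI = %.4g", object$mi)) +
    ggplot2::theme_minimal()
}

#' Plot detected ripple events over rest time
#'
#' @param object A `ripple_events` tibble from [detect_ripples()].
#' @param ... Unused.
#' @export
autoplot.ripple_events <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$peak_s,
                                       y = .data$amplitude_sd)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$peak_s, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (s)", y = "Envelope amplitude (SD)") +
    ggplot2::theme_minimal()
}
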