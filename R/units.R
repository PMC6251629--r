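# Putative cell-type classification for sorted single units.

#' Classify a single unit as pyramidal cell or interneuron
#'
#' Pyramidal cells have broad waveforms (peak-to-valley width > 300 us),
#' low baseline firing rates (< 5 Hz) and burst firing (autocorrelogram
#' peak within 10 ms); interneurons are narrow (<= 300 us) and fast
#' (>= 5 Hz). Units matching neither profile are left unclassified.
#'
#' @param spike_times_s Sorted spike times in seconds.
#' @param waveform Mean spike waveform (voltage samples at the electrode
#'   with the largest amplitude).
#' @param wf_rate_hz Waveform sampling rate (e.g. 30000).
#' @param baseline Baseline interval `c(start_s, end_s)` for the firing
#'   rate; defaults to the full span of the spike train.
#' @param min_spikes Minimum baseline spike count (default 50).
#' @return One-row tibble: `label` (`pyramidal`/`interneuron`/
#'   `unclassified`), `spike_width_us`, `mean_rate_hz`, `burst_lag_ms`,
#'   `reason`.
#' @export
classify_unit <- function(spike_times_s, waveform, wf_rate_hz,
                          baseline = range(spike_times_s), min_spikes = 50) {
  if (is.unsorted(spike_times_s, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  in_base <- spike_times_s >= baseline[1] & spike_times_s < baseline[2]
  n_base <- sum(in_base)
  width <- spike_width_us(waveform, wf_rate_hz)
  if (n_base < min_spikes) {
    return(tibble::tibble(label = "unclassified", spike_width_us = width,
                          mean_rate_hz = NA_real_, burst_lag_ms = NA_real_,
                          reason = sprintf("only %d baseline spikes", n_base)))
  }
  rate <- n_base / (baseline[2] - baseline[1])
  burst <- autocorr_peak_lag_ms(spike_times_s)
  label <- if (width > 300 && rate < 5 && !is.na(burst) && burst <= 10) {
    "pyramidal"
  } else if (width <= 300 && rate >= 5) {
    "interneuron"
  } else {
    "unclassified"
  }
  tibble::tibble(label = label, spike_width_us = width, mean_rate_hz = rate,
                 burst_lag_ms = burst, reason = NA_character_)
}

# Peak-to-valley width of the mean waveform, in microseconds. Amplitude
# scaling leaves the argmax/argmin untouched, so the result is invariant
# to gain.
spike_width_us <- function(waveform, wf_rate_hz) {
  w <- as.numeric(waveform)
  pk <- which.max(w)
  if (pk >= length(w)) return(NA_real_)
  vl <- pk - 1L + which.min(w[pk:length(w)])
  (vl - pk) / wf_rate_hz * 1e6
}

# Lag (ms) of the global maximum of the +/-50 ms spike autocorrelogram
# (1-ms bins), excluding the 0-1.5 ms refractory bins.
autocorr_peak_lag_ms <- function(spike_times_s, max_lag_ms = 50,
                                 bin_ms = 1, refractory_ms = 1.5) {
  n <- length(spike_times_s)
  max_lag <- max_lag_ms / 1000
  d <- numeric(0)
  k <- 1L
  repeat {
    if (k >= n) break
    dk <- spike_times_s[(1 + k):n] - spike_times_s[1:(n - k)]
    dk <- dk[dk <= max_lag]
    if (length(dk) == 0) break
    d <- c(d, dk)
    k <- k + 1L
  }
  d <- d[d > refractory_ms / 1000]
  if (length(d) == 0) return(NA_real_)
  breaks <- seq(0, max_lag_ms, by = bin_ms)
  h <- graphics::hist(d * 1000, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Firing-rate time course
#'
#' Spike counts per bin divided by the bin width.
#'
#' @param spike_times_s Spike times in seconds.
#' @param bin_s Bin width in seconds.
#' @param t_range Time range `c(start, end)`; defaults to `[0, max)`.
#' @return A tibble with columns `time_s` (bin center) and `rate_hz`.
#' @export
firing_rate_timecourse <- function(spike_times_s, bin_s,
                                   t_range = c(0, max(spike_times_s))) {
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  n_bins <- max(1L, ceiling((t_range[2] - t_range[1]) / bin_s - 1e-9))
  breaks <- t_range[1] + (0:n_bins) * bin_s
  cnt <- graphics::hist(spike_times_s[spike_times_s >= t_range[1] &
                                        spike_times_s < t_range[2]],
                        breaks = breaks, plot = FALSE)$counts
  tibble::tibble(time_s = utils::head(breaks, -1) + bin_s / 2,
                 rate_hz = cnt / bin_s)
}
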