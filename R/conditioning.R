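# Per-state z-scoring, zero-phase filtering and analytic-signal
# extraction shared by every downstream stage.

#' Z-score an LFP within each behavioral state
#'
#' For each state label present in `segments`, gathers all samples of
#' that state (interval edges rounded inward onto the LFP grid),
#' transforms the concatenated subset to mean 0 / SD 1 using the subset's
#' own statistics, and returns the segment-aligned pieces. Z-scoring the
#' run and rest subsets separately controls for changes in overall signal
#' amplitude across recordings.
#'
#' @param lfp An [as_lfp()] tibble.
#' @param segments A [new_segments()] tibble.
#' @return A tibble of class `state_lfp` with columns `time_s`,
#'   `voltage`, `state`, `bout`; attribute `lfp_rate` carries the rate.
#' @export
zscore_by_state <- function(lfp, segments) {
  rate <- lfp_rate(lfp)
  n <- nrow(lfp)
  t0 <- lfp$time_s[1]
  pieces <- list()
  for (st in unique(segments$state)) {
    seg <- segments[segments$state == st, ]
    idx_list <- lapply(seq_len(nrow(seg)), function(i) {
      interval_indices(seg$start_s[i] - t0, seg$end_s[i] - t0, rate, n)
    })
    keep <- lengths(idx_list) > 0
    idx_list <- idx_list[keep]
    all_idx <- unlist(idx_list)
    if (length(all_idx) < rate) {
      stop(sprintf("state '%s' has < 1 s of samples; cannot z-score", st),
           call. = FALSE)
    }
    v <- lfp$voltage[all_idx]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population SD: z-scoring is exact
    if (s == 0) stop(sprintf("state '%s' subset has zero variance", st),
                     call. = FALSE)
    pieces[[st]] <- purrr::map_dfr(seq_along(idx_list), function(i) {
      idx <- idx_list[[i]]
      tibble::tibble(time_s = lfp$time_s[idx],
                     voltage = (lfp$voltage[idx] - m) / s,
                     state = st,
                     bout = i)
    })
  }
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$time_s)
  structure(out, class = c("state_lfp", class(out)), lfp_rate = rate)
}

# Split a state_lfp into per-bout numeric vectors for one state.
state_bouts <- function(z, state) {
  sub <- z[z$state == state, ]
  if (nrow(sub) == 0) return(list())
  unname(split(sub$voltage, sub$bout))
}

# Internal zero-phase Butterworth band-pass on a numeric vector.
butter_bandpass <- function(x, rate, low, high, order = 4) {
  ny <- rate / 2
  if (!(low > 0 && low < high && high < ny)) {
    stop(sprintf("band %g-%g Hz invalid for rate %g Hz", low, high, rate),
         call. = FALSE)
  }
  sos <- butter_bp_sos(order, low / ny, high / ny)
  filtfilt_pad(sos$b, sos$a, x, pad = sos$pad)
}

# Internal zero-phase FIR band-pass (Hamming-window design).
fir_bandpass <- function(x, rate, low, high, order = 69) {
  ny <- rate / 2
  if (!(low > 0 && low < high && high < ny)) {
    stop(sprintf("band %g-%g Hz invalid for rate %g Hz", low, high, rate),
         call. = FALSE)
  }
  b <- signal::fir1(order, c(low, high) / ny, type = "pass")
  filtfilt_pad(as.numeric(b), 1, x, pad = 3L * (order + 1L))
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (effective 8th
#' order, zero group delay), with odd-reflection padding to suppress edge
#' transients. The ripple band uses a dedicated 69-order FIR design (see
#' [detect_ripples()]); this function is the band filter for theta/gamma
#' analyses.
#'
#' @param lfp An [as_lfp()] tibble or numeric vector.
#' @param band Band name (see [lfp_bands()]) or `c(low, high)` in Hz.
#' @param rate Sampling rate; taken from `lfp` when omitted.
#' @param order Butterworth order (applied twice).
#' @return Same shape as the input (lfp tibble or numeric vector).
#' @export
bandpass_zero_phase <- function(lfp, band, rate = NULL, order = 4) {
  bd <- band_def(band)
  if (is.data.frame(lfp)) {
    rate <- rate %||% lfp_rate(lfp)
    y <- butter_bandpass(lfp$voltage, rate, bd$low_hz, bd$high_hz, order)
    out <- lfp
    out$voltage <- y
    return(out)
  }
  butter_bandpass(as.numeric(lfp), rate, bd$low_hz, bd$high_hz, order)
}

#' Zero-phase IIR notch filter
#'
#' Cascaded biquad notches (constant-Q design) at the given frequencies,
#' applied forward-backward. Defaults remove 60 Hz mains and its 180 Hz
#' harmonic.
#'
#' @param lfp An [as_lfp()] tibble or numeric vector.
#' @param freqs Notch frequencies in Hz.
#' @param q Notch quality factor (center frequency / -3 dB bandwidth).
#' @param rate Sampling rate; taken from `lfp` when omitted.
#' @return Same shape as the input.
#' @export
notch_filter <- function(lfp, freqs = c(60, 180), q = 30, rate = NULL) {
  if (is.data.frame(lfp)) {
    rate <- rate %||% lfp_rate(lfp)
    out <- lfp
    out$voltage <- notch_filter(lfp$voltage, freqs = freqs, q = q, rate = rate)
    return(out)
  }
  x <- as.numeric(lfp)
  if (any(freqs >= rate / 2)) {
    stop("notch frequencies must be below Nyquist", call. = FALSE)
  }
  for (f0 in freqs) {
    w0 <- 2 * pi * f0 / rate
    alpha <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    x <- filtfilt_pad(b / a[1], a / a[1], x,
                      pad = as.integer(round(2 * rate * q / f0)))
  }
  x
}

#' Analytic signal: envelope and instantaneous phase
#'
#' Hilbert-transforms a band-limited signal and returns the modulus
#' (envelope) and argument (phase) of the analytic extension. Phase 0
#' falls at the positive peak of the band-filtered oscillation. The first
#' and last 100 ms are flagged edge-invalid.
#'
#' @param x Band-pass filtered numeric vector or lfp tibble.
#' @param rate Sampling rate; taken from `x` when omitted.
#' @param edge_s Edge-invalid margin in seconds.
#' @return A tibble with columns `envelope`, `phase` (radians,
#'   `(-pi, pi]`) and `edge_valid`.
#' @export
analytic_signal <- function(x, rate = NULL, edge_s = 0.1) {
  if (is.data.frame(x)) {
    rate <- rate %||% lfp_rate(x)
    x <- x$voltage
  }
  if (is.null(rate)) stop("rate is required for vector input", call. = FALSE)
  z <- analytic_fft(as.numeric(x))
  n <- length(x)
  m <- min(n %/% 2, as.integer(round(edge_s * rate)))
  valid <- rep(TRUE, n)
  if (m > 0) {
    valid[seq_len(m)] <- FALSE
    valid[(n - m + 1):n] <- FALSE
  }
  tibble::tibble(envelope = Mod(z), phase = Arg(z), edge_valid = valid)
}
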