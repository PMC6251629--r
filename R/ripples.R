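# Sharp-wave ripple detection.
#
# Per rest bout of the z-scored pyramidal-layer LFP: 60/180 Hz notch ->
# 69-order FIR zero-phase band-pass 100-300 Hz -> analytic envelope ->
# 50-ms moving-average smoothing. The threshold (envelope mean + 3 SD)
# is computed once over all analyzed rest samples, so it is stable
# across bouts. Maximal supra-threshold runs longer than 30 ms become
# candidate events; a candidate starting within 200 ms of the previous
# accepted event's offset is discarded, and events touching the 100-ms
# edge-invalid margins of a bout are dropped.

#' Ripple detection parameters
#'
#' @param notch_freqs Line-noise notch frequencies (Hz).
#' @param band Ripple band `c(low, high)` in Hz.
#' @param fir_order Order of the zero-phase FIR band-pass.
#' @param smooth_window_ms Envelope smoothing window (ms).
#' @param threshold_sd Detection threshold in SDs above the mean
#'   smoothed-envelope amplitude.
#' @param min_duration_ms Minimum supra-threshold duration (ms,
#'   exclusive).
#' @param refractory_ms Minimum gap from the previous accepted event's
#'   offset to the next onset (ms).
#' @return A list of class `ripple_params`.
#' @export
ripple_params <- function(notch_freqs = c(60, 180), band = c(100, 300),
                          fir_order = 69, smooth_window_ms = 50,
                          threshold_sd = 3, min_duration_ms = 30,
                          refractory_ms = 200) {
  p <- as.list(environment())
  if (any(unlist(p[c("fir_order", "smooth_window_ms", "threshold_sd",
                     "min_duration_ms", "refractory_ms")]) <= 0)) {
    stop("ripple parameters must be positive", call. = FALSE)
  }
  structure(p, class = "ripple_params")
}

#' Detect sharp-wave ripples in rest-state LFP
#'
#' @param z A `state_lfp` from [zscore_by_state()] (its `"rest"` bouts
#'   are analyzed), or an [as_lfp()] tibble together with `segments`.
#' @param segments Required when `z` is a plain LFP: rest segments to
#'   analyze.
#' @param params A [ripple_params()] list.
#' @param edge_s Edge-invalid margin per bout (s).
#' @return A tibble of class `ripple_events` with columns `onset_s`,
#'   `offset_s`, `peak_s`, `amplitude_sd`, `duration_ms`, sorted by
#'   onset; attributes `threshold`, `env_mean`, `env_sd`,
#'   `analyzed_time_s`, `n_dropped_edge`, `n_dropped_refractory`.
#' @export
detect_ripples <- function(z, segments = NULL, params = ripple_params(),
                           edge_s = 0.1) {
  if (!inherits(z, "state_lfp")) {
    if (is.null(segments)) {
      stop("segments are required for plain LFP input", call. = FALSE)
    }
    z <- zscore_by_state(z, segments[segments$state == "rest", ])
  }
  rate <- lfp_rate(z)
  if (params$band[2] >= rate / 2) {
    stop("ripple band extends to or beyond Nyquist", call. = FALSE)
  }
  sub <- z[z$state == "rest", ]
  if (nrow(sub) == 0) stop("no rest samples to analyze", call. = FALSE)
  total_s <- nrow(sub) / rate
  if (total_s < 10) {
    stop(sprintf(
      "only %.1f s of rest data; at least 10 s needed for a stable threshold",
      total_s), call. = FALSE)
  }
  bouts <- split(sub, sub$bout)
  margin <- as.integer(round(edge_s * rate))
  smooth_n <- as.integer(round(params$smooth_window_ms / 1000 * rate))

  env_list <- lapply(bouts, function(b) {
    v <- notch_filter(b$voltage, freqs = params$notch_freqs, rate = rate)
    v <- fir_bandpass(v, rate, params$band[1], params$band[2],
                      order = params$fir_order)
    env <- analytic_signal(v, rate, edge_s = edge_s)$envelope
    moving_average(env, smooth_n)
  })
  pooled <- unlist(lapply(env_list, function(e) {
    n <- length(e)
    if (n > 2 * margin) e[(margin + 1):(n - margin)] else numeric(0)
  }))
  mu <- mean(pooled)
  sdv <- stats::sd(pooled)
  thr <- mu + params$threshold_sd * sdv

  min_n <- as.integer(round(params$min_duration_ms / 1000 * rate))
  ev <- list()
  n_edge <- 0L
  for (b in seq_along(bouts)) {
    e <- env_list[[b]]
    tt <- bouts[[b]]$time_s
    above <- e > thr
    if (!any(above)) next
    rr <- rle(above)
    ends <- cumsum(rr$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    for (j in which(rr$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      if (i1 - i0 + 1L <= min_n) next  # must exceed min duration
      if (i0 <= margin || i1 > length(e) - margin) {
        n_edge <- n_edge + 1L
        log_stage("ripples", sprintf(
          "candidate at %.3f s dropped: overlaps bout edge margin", tt[i0]))
        next
      }
      pk <- i0 - 1L + which.max(e[i0:i1])
      ev[[length(ev) + 1L]] <- tibble::tibble(
        onset_s = tt[i0], offset_s = tt[i1] + 1 / rate, peak_s = tt[pk],
        amplitude_sd = (e[pk] - mu) / sdv,
        duration_ms = (i1 - i0 + 1L) / rate * 1000)
    }
  }
  events <- dplyr::bind_rows(ev)
  n_refr <- 0L
  if (nrow(events) > 0) {
    events <- events[order(events$onset_s), ]
    keep <- logical(nrow(events))
    last_off <- -Inf
    for (i in seq_len(nrow(events))) {
      if (events$onset_s[i] - last_off > params$refractory_ms / 1000) {
        keep[i] <- TRUE
        last_off <- events$offset_s[i]
      } else {
        n_refr <- n_refr + 1L
      }
    }
    events <- events[keep, ]
  } else {
    events <- tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                             peak_s = numeric(), amplitude_sd = numeric(),
                             duration_ms = numeric())
  }
  # Post-condition: accepted events honor the refractory rule.
  if (nrow(events) > 1) {
    stopifnot(all(events$onset_s[-1] - events$offset_s[-nrow(events)] >
                    params$refractory_ms / 1000))
  }
  structure(events, class = c("ripple_events", class(events)),
            threshold = thr, env_mean = mu, env_sd = sdv,
            analyzed_time_s = total_s, n_dropped_edge = n_edge,
            n_dropped_refractory = n_refr, params = params)
}

#' Ripple event-rate and amplitude summary
#'
#' @param events A `ripple_events` tibble from [detect_ripples()].
#' @param segments Rest segments analyzed (used for the time base when
#'   the events object lacks an `analyzed_time_s` attribute).
#' @return One-row tibble of class `ripple_stats`: `n_events`,
#'   `analyzed_time_s`, `event_rate_hz`, `mean_amplitude_sd` (NA when no
#'   events were found).
#' @export
ripple_stats <- function(events, segments = NULL) {
  at <- attr(events, "analyzed_time_s")
  if (is.null(at)) {
    if (is.null(segments)) stop("segments needed to establish time base", call. = FALSE)
    rest <- segments[segments$state == "rest", ]
    at <- sum(rest$end_s - rest$start_s)
  }
  if (at <= 0) stop("zero analyzed rest time", call. = FALSE)
  tibble::tibble(
    n_events = nrow(events),
    analyzed_time_s = at,
    event_rate_hz = nrow(events) / at,
    mean_amplitude_sd = if (nrow(events) > 0) mean(events$amplitude_sd) else NA_real_
  )
}
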