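# Running-speed estimation and run/rest state segmentation.

#' Compute running speed from a position trace
#'
#' Positions are smoothed with a centered moving average (default 0.5 s)
#' before differentiating; speed is the Euclidean norm of central finite
#' differences, with one-sided differences at the boundaries.
#'
#' @param pos Position tibble with columns `time_s`, `x_cm`, `y_cm`.
#' @param smooth_s Width of the position smoothing window in seconds.
#' @return A tibble with columns `time_s`, `speed_cm_s` on the same grid
#'   as the input.
#' @export
compute_velocity <- function(pos, smooth_s = 0.5) {
  if (nrow(pos) < 2) stop("need at least 2 position samples", call. = FALSE)
  tt <- pos$time_s
  if (any(diff(tt) <= 0)) {
    stop("position timestamps must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  rate <- 1 / stats::median(diff(tt))
  w <- max(1L, as.integer(round(smooth_s * rate)))
  x <- moving_average(pos$x_cm, w)
  y <- moving_average(pos$y_cm, w)
  n <- length(tt)
  vx <- vy <- numeric(n)
  if (n > 2) {
    ctr <- 2:(n - 1)
    dt2 <- tt[ctr + 1] - tt[ctr - 1]
    vx[ctr] <- (x[ctr + 1] - x[ctr - 1]) / dt2
    vy[ctr] <- (y[ctr + 1] - y[ctr - 1]) / dt2
  }
  vx[1] <- (x[2] - x[1]) / (tt[2] - tt[1])
  vy[1] <- (y[2] - y[1]) / (tt[2] - tt[1])
  vx[n] <- (x[n] - x[n - 1]) / (tt[n] - tt[n - 1])
  vy[n] <- (y[n] - y[n - 1]) / (tt[n] - tt[n - 1])
  tibble::tibble(time_s = tt, speed_cm_s = sqrt(vx^2 + vy^2))
}

#' Divide a session into run and rest segments
#'
#' Samples at or above `run_min_cm_s` (default 7 cm/s) are running;
#' samples below `rest_max_cm_s` (default 0.5 cm/s) are resting;
#' intermediate speeds belong to neither state. Maximal same-state
#' stretches at least `min_bout_s` long become segments, and each rest
#' bout is truncated to its first `rest_cap_s` seconds (immobility
#' periods are analyzed for up to 20 s after the animal stops moving).
#'
#' @param vel Velocity tibble from [compute_velocity()].
#' @param run_min_cm_s Running threshold (inclusive), cm/s.
#' @param rest_max_cm_s Resting threshold (exclusive), cm/s.
#' @param rest_cap_s Maximum analyzed length of a rest bout, seconds.
#' @param min_bout_s Minimum bout duration, seconds.
#' @return A [new_segments()] tibble; thresholds stored as attributes.
#' @export
segment_states <- function(vel, run_min_cm_s = 7, rest_max_cm_s = 0.5,
                           rest_cap_s = 20, min_bout_s = 1) {
  if (nrow(vel) == 0) stop("empty velocity trace", call. = FALSE)
  if (rest_max_cm_s >= run_min_cm_s) {
    stop("rest_max_cm_s must be below run_min_cm_s", call. = FALSE)
  }
  tt <- vel$time_s
  dt <- stats::median(diff(tt))
  lab <- ifelse(vel$speed_cm_s >= run_min_cm_s, "run",
                ifelse(vel$speed_cm_s < rest_max_cm_s, "rest", "none"))
  rr <- rle(lab)
  ends_i <- cumsum(rr$lengths)
  starts_i <- c(1L, ends_i[-length(ends_i)] + 1L)
  keep <- rr$values != "none"
  st <- tt[starts_i[keep]]
  # Half-open: a bout ends one sample period after its last sample.
  en <- tt[ends_i[keep]] + dt
  state <- rr$values[keep]
  dur <- en - st
  ok <- dur >= min_bout_s - 1e-9
  st <- st[ok]; en <- en[ok]; state <- state[ok]
  cap <- state == "rest" & (en - st) > rest_cap_s
  en[cap] <- st[cap] + rest_cap_s
  out <- new_segments(st, en, state)
  attr(out, "thresholds") <- list(run_min_cm_s = run_min_cm_s,
                                  rest_max_cm_s = rest_max_cm_s,
                                  rest_cap_s = rest_cap_s,
                                  min_bout_s = min_bout_s)
  out
}

#' Clip segments to an analysis window
#'
#' Intersects every segment with the half-open window `[start, end)`,
#' e.g. the 30-60 min interval following a treatment. An empty result is
#' allowed.
#'
#' @param segments A [new_segments()] tibble.
#' @param window Numeric `c(start_s, end_s)`.
#' @return A clipped [new_segments()] tibble.
#' @export
restrict_to_window <- function(segments, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  st <- pmax(segments$start_s, window[1])
  en <- pmin(segments$end_s, window[2])
  keep <- en > st
  out <- new_segments(st[keep], en[keep], segments$state[keep])
  attr(out, "thresholds") <- attr(segments, "thresholds")
  out
}

#' Locomotion summary for a session
#'
#' Percent of window time spent running and mean speed during run
#' segments.
#'
#' @param vel Velocity tibble.
#' @param segments Segments already restricted to the analysis window.
#' @param window Numeric `c(start_s, end_s)` analysis window.
#' @return One-row tibble: `percent_time_running`, `mean_run_speed_cm_s`,
#'   `run_time_s`, `rest_time_s`.
#' @export
locomotion_summary <- function(vel, segments, window = range(vel$time_s)) {
  run <- segments[segments$state == "run", ]
  rest <- segments[segments$state == "rest", ]
  run_t <- sum(run$end_s - run$start_s)
  in_run <- rep(FALSE, nrow(vel))
  for (i in seq_len(nrow(run))) {
    in_run <- in_run | (vel$time_s >= run$start_s[i] & vel$time_s < run$end_s[i])
  }
  tibble::tibble(
    percent_time_running = 100 * run_t / (window[2] - window[1]),
    mean_run_speed_cm_s = if (any(in_run)) mean(vel$speed_cm_s[in_run]) else NA_real_,
    run_time_s = run_t,
    rest_time_s = sum(rest$end_s - rest$start_s)
  )
}
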