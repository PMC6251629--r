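#' Construct an LFP trace tibble
#'
#' The package represents a continuous local field potential trace as a
#' tibble with columns `time_s` and `voltage`, carrying the sampling rate
#' and channel role (`"hpc"` or `"pfc"`) as attributes. Times are seconds
#' from session start; all intervals in the package are half-open
#' `[start, end)`.
#'
#' @param x Numeric vector of samples, or a data frame with columns
#'   `time_s` and `voltage`.
#' @param rate Sampling rate in Hz. Required when `x` is a bare vector;
#'   when `x` has a `time_s` column the rate is checked against it.
#' @param role Optional channel role, one of `"hpc"`, `"pfc"`.
#' @param t0 Time of the first sample in seconds (vector input only).
#' @param zscored Logical flag recording whether the trace has been
#'   z-scored.
#' @return A tibble of class `lfp_tbl` with columns `time_s`, `voltage`.
#' @examples
#' lfp <- as_lfp(sin(2 * pi * 7 * seq(0, 1, by = 1e-3)), rate = 1000)
#' lfp_rate(lfp)
#' @export
as_lfp <- function(x, rate = NULL, role = NULL, t0 = 0, zscored = FALSE) {
  if (is.data.frame(x)) {
    if (!all(c("time_s", "voltage") %in% names(x))) {
      stop("data frame input must have columns time_s and voltage", call. = FALSE)
    }
    tt <- x$time_s
    if (length(tt) >= 2) {
      dt <- diff(tt)
      if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
      inferred <- 1 / stats::median(dt)
      if (is.null(rate)) rate <- inferred
      else if (abs(rate - inferred) / rate > 0.01) {
        stop(sprintf("declared rate %g Hz inconsistent with time stamps (~%g Hz)",
                     rate, inferred), call. = FALSE)
      }
    }
    out <- tibble::tibble(time_s = as.numeric(tt), voltage = as.numeric(x$voltage))
  } else {
    if (is.null(rate)) stop("rate is required for vector input", call. = FALSE)
    x <- as.numeric(x)
    out <- tibble::tibble(time_s = t0 + (seq_along(x) - 1) / rate, voltage = x)
  }
  if (anyNA(out$voltage)) {
    bad <- which(is.na(out$voltage))
    stop(sprintf("signal contains %d NA/NaN sample(s), first at index %d",
                 length(bad), bad[1]), call. = FALSE)
  }
  if (!is.null(role)) role <- match.arg(role, c("hpc", "pfc"))
  structure(out,
            class = c("lfp_tbl", class(out)),
            lfp_rate = as.numeric(rate),
            lfp_role = role,
            lfp_zscored = isTRUE(zscored))
}

#' @rdname as_lfp
#' @param lfp An `lfp_tbl` or a plain data frame with a `time_s` column.
#' @export
lfp_rate <- function(lfp) {
  r <- attr(lfp, "lfp_rate")
  if (!is.null(r)) return(r)
  tt <- lfp$time_s
  if (is.null(tt) || length(tt) < 2) stop("cannot infer sampling rate", call. = FALSE)
  1 / stats::median(diff(tt))
}

#' @rdname as_lfp
#' @export
lfp_role <- function(lfp) attr(lfp, "lfp_role")

#' Canonical frequency bands
#'
#' The oscillation bands used throughout the pipeline: theta 5-10 Hz,
#' low-gamma 30-60 Hz, high-gamma 65-100 Hz, the narrower 30-55 Hz
#' low-gamma band used for phase-amplitude coupling, and the 100-300 Hz
#' ripple band.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' lfp_bands()
#' band_def("lowgamma")
#' @export
lfp_bands <- function() {
  tibble::tibble(
    band    = c("theta", "lowgamma", "highgamma", "cfc_lowgamma", "ripple"),
    low_hz  = c(5, 30, 65, 30, 100),
    high_hz = c(10, 60, 100, 55, 300)
  )
}

#' @rdname lfp_bands
#' @param band Band name (see `lfp_bands()`) or a numeric `c(low, high)`
#'   pair in Hz.
#' @export
band_def <- function(band) {
  if (is.numeric(band) && length(band) == 2) {
    lo <- band[1]; hi <- band[2]
    if (!(lo > 0 && lo < hi)) {
      stop("numeric band must satisfy 0 < low < high", call. = FALSE)
    }
    return(tibble::tibble(band = sprintf("%g-%g Hz", lo, hi),
                          low_hz = lo, high_hz = hi))
  }
  tab <- lfp_bands()
  hit <- tab[tab$band == band, ]
  if (nrow(hit) != 1) {
    stop(sprintf("unknown band '%s'; see lfp_bands()", band), call. = FALSE)
  }
  hit
}

#' Construct a state-segment tibble
#'
#' Behavioral state segments are tibbles with columns `start_s`, `end_s`
#' and `state` (`"run"` or `"rest"`), time-sorted and non-overlapping,
#' with half-open intervals `[start_s, end_s)`.
#'
#' @param start_s,end_s Numeric interval bounds in seconds.
#' @param state Character vector of labels (`"run"`/`"rest"`).
#' @return A tibble of class `state_segments`.
#' @export
new_segments <- function(start_s = numeric(), end_s = numeric(),
                         state = character()) {
  stopifnot(length(start_s) == length(end_s), length(state) == length(start_s))
  if (any(end_s <= start_s)) stop("segments must have end_s > start_s", call. = FALSE)
  out <- tibble::tibble(start_s = as.numeric(start_s),
                        end_s = as.numeric(end_s),
                        state = as.character(state))
  out <- out[order(out$start_s), ]
  if (nrow(out) > 1 && any(out$start_s[-1] < out$end_s[-nrow(out)] - 1e-12)) {
    stop("segments must be non-overlapping", call. = FALSE)
  }
  structure(out, class = c("state_segments", class(out)))
}

# Sample indices (on a uniform grid at `rate` starting at t = 0) covered
# by a half-open interval, with edges rounded inward.
interval_indices <- function(start_s, end_s, rate, n) {
  i0 <- max(1L, as.integer(ceiling(start_s * rate - 1e-9)) + 1L)
  i1 <- min(n, as.integer(floor(end_s * rate + 1e-9)))
  if (i1 < i0) return(integer())
  seq.int(i0, i1)
}
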