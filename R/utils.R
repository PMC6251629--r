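# Internal numerical primitives shared across the pipeline.

# Environment-level cache for DPSS tapers; keyed by "n_nw_k".
.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw`, as the leading eigenvectors of the standard symmetric
#' tridiagonal commuting matrix. Tapers are unit-energy
#' (`sum(taper^2) == 1`) and sign-fixed so that each taper has a
#' non-negative mean (even orders) or non-negative initial slope (odd
#' orders), matching the usual convention.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (e.g. 3 for a 5-taper estimate).
#' @param k Number of tapers to return; must satisfy `k <= 2*nw - 1` for
#'   well-concentrated tapers.
#' @return An `n` x `k` matrix, one taper per column, ordered by
#'   decreasing spectral concentration.
#' @keywords internal
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k < n)
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  A <- diag(dg)
  A[cbind(2:n, 1:(n - 1))] <- od
  A[cbind(1:(n - 1), 2:n)] <- od
  ev <- eigen(A, symmetric = TRUE)
  tp <- ev$vectors[, seq_len(k), drop = FALSE]
  # Fix signs: even-order tapers positive mean, odd-order positive slope.
  for (j in seq_len(k)) {
    s <- if (j %% 2 == 1) sum(tp[, j]) else sum(diff(tp[, j])[seq_len(n %/% 2)])
    if (s < 0) tp[, j] <- -tp[, j]
  }
  tp <- sweep(tp, 2, sqrt(colSums(tp^2)), "/")
  .taper_cache[[key]] <- tp
  tp
}

# Analytic signal by FFT half-spectrum doubling. Returns complex vector.
analytic_fft <- function(x) {
  n <- length(x)
  if (n < 2) stop("analytic signal requires at least 2 samples", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Odd (antisymmetric) reflection padding, as used before zero-phase
# filtering to suppress edge transients.
reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1)
  if (p <= 0) return(list(x = x, p = 0L))
  head_pad <- 2 * x[1] - rev(x[2:(p + 1)])
  tail_pad <- 2 * x[n] - rev(x[(n - p):(n - 1)])
  list(x = c(head_pad, x, tail_pad), p = as.integer(p))
}

# Forward-backward (zero-phase) application of a rational filter with
# odd-reflection padding. `b`, `a` are numerator/denominator
# coefficients, or parallel lists of them (a cascade of sections).
filtfilt_pad <- function(b, a, x, pad = NULL) {
  if (!is.list(b)) { b <- list(b); a <- list(a) }
  n <- length(x)
  if (is.null(pad)) pad <- 3L * max(vapply(b, length, 1L), vapply(a, length, 1L))
  pp <- reflect_pad(x, pad)
  y <- pp$x
  for (s in seq_along(b)) y <- as.numeric(signal::filter(b[[s]], a[[s]], y))
  y <- rev(y)
  for (s in seq_along(b)) y <- as.numeric(signal::filter(b[[s]], a[[s]], y))
  y <- rev(y)
  y[(pp$p + 1):(pp$p + n)]
}

# Butterworth band-pass as second-order sections. Narrow bands at low
# normalized frequency are numerically unstable in direct form; the
# biquad cascade keeps each section well conditioned. Each conjugate
# pole pair is matched with one zero at z = 1 and one at z = -1.
butter_bp_sos <- function(order, w_low, w_high) {
  flt <- signal::butter(order, c(w_low, w_high), type = "pass")
  a <- as.numeric(flt$a) / flt$a[1]
  k <- as.numeric(flt$b)[1] / flt$a[1]
  poles <- polyroot(rev(a))
  up <- poles[Im(poles) > 0]
  if (length(up) != order) {
    # degenerate design with real poles: pair sequentially by modulus
    up <- poles[order(-Mod(poles))][seq(1, 2 * order, by = 2)]
  }
  bs <- vector("list", length(up))
  as_ <- vector("list", length(up))
  for (i in seq_along(up)) {
    p <- up[i]
    as_[[i]] <- c(1, -2 * Re(p), Mod(p)^2)
    bs[[i]] <- c(1, 0, -1) * if (i == 1) k else 1
  }
  # Pad long enough for the slowest pole's transient to fall below 1e-13.
  pad <- ceiling(log(1e-13) / log(min(max(Mod(poles)), 1 - 1e-9)))
  list(b = bs, a = as_, pad = as.integer(pad))
}

# Centered moving average with truncated (renormalized) edges.
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1) return(x)
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Wrap angles to [0, 2*pi).
wrap_2pi <- function(x) x %% (2 * pi)

# Evaluate a block with a private RNG stream, restoring the caller's
# .Random.seed afterwards so simulation never perturbs user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Structured stage logging, silenced unless options(lfpkit.verbose = TRUE).
log_stage <- function(stage, msg) {
  if (isTRUE(getOption("lfpkit.verbose", FALSE))) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS3"), stage, msg))
  }
  invisible(NULL)
}
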