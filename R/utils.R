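# Internal numeric helpers shared across modules.

#' Moving-window statistic with strided evaluation
#'
#' Computes `stat_fun` over centered windows (truncated at the edges) at a
#' strided set of anchor points and linearly interpolates between anchors.
#' Slow-baseline statistics (percentile filters, moving medians, moving noise
#' s.d.) vary on timescales of seconds to minutes, so evaluating every sample
#' would waste almost all the work; the stride defaults to 1/16 of the window.
#'
#' @param x numeric vector.
#' @param width window width in samples (>= 1).
#' @param stat_fun function mapping a numeric vector (possibly with NAs
#'   removed) to a scalar, or NA when the window is empty/degenerate.
#' @param stride anchor spacing in samples.
#' @return numeric vector, `length(x)`.
#' @keywords internal
#' @noRd
moving_stat <- function(x, width, stat_fun, stride = max(1L, width %/% 16L)) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  half <- width %/% 2L
  anchors <- unique(c(seq(1L, n, by = as.integer(stride)), n))
  vals <- vapply(anchors, function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    stat_fun(w)
  }, numeric(1))
  ok <- is.finite(vals)
  if (!any(ok)) stop("moving_stat: statistic undefined in every window")
  if (sum(ok) == 1L) return(rep(vals[ok], n))
  stats::approx(anchors[ok], vals[ok], xout = seq_len(n), rule = 2)$y
}

#' Discrete Gaussian smoothing kernel specified by FWHM
#' @keywords internal
#' @noRd
gaussian_kernel <- function(fwhm_s, dt) {
  sigma <- fwhm_s / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / dt))
  tt <- seq(-half, half) * dt
  k <- exp(-tt^2 / (2 * sigma^2))
  k / sum(k)
}

#' Place unit-mass smoothing kernels at event frames
#'
#' Each event contributes a kernel clipped to the trace bounds and
#' renormalized to unit mass, so that `sum(rate) * dt` equals the event count
#' exactly regardless of edge proximity.
#' @keywords internal
#' @noRd
kernel_rate <- function(event_frames, n_frames, kernel, dt) {
  rate <- numeric(n_frames)
  if (length(event_frames) == 0L) return(rate)
  half <- (length(kernel) - 1L) %/% 2L
  for (f in event_frames) {
    lo <- max(1L, f - half)
    hi <- min(n_frames, f + half)
    kseg <- kernel[(lo - f + half + 1L):(hi - f + half + 1L)]
    rate[lo:hi] <- rate[lo:hi] + kseg / (sum(kseg) * dt)
  }
  rate
}

#' Single-exponential (calcium indicator) convolution
#'
#' Recursive implementation of convolution with `exp(-t/tau)` sampled at
#' `dt`. `normalize = "peak"` makes a unit impulse produce a transient of
#' peak 1 (spike-train semantics); `normalize = "area"` gives the kernel
#' unit area so sustained firing-rate-like input keeps its amplitude
#' (DC gain 1).
#' @keywords internal
#' @noRd
calcium_convolve <- function(x, dt, tau_s,
                             normalize = c("area", "peak")) {
  normalize <- match.arg(normalize)
  a <- exp(-dt / tau_s)
  y <- as.numeric(stats::filter(x, a, method = "recursive", init = 0))
  if (normalize == "area") y * (1 - a) else y
}

#' Correlated-plus-white fluorescence measurement noise
#'
#' Unit-variance mixture: `sqrt(w)` white + `sqrt(1-w)` AR(1) with time
#' constant `tau_s` (itself scaled to unit variance).
#' @keywords internal
#' @noRd
fluor_noise <- function(n, dt, tau_s, white_frac = 0.2) {
  a <- exp(-dt / tau_s)
  ar <- as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - a^2)), a,
                                 method = "recursive", init = 0))
  sqrt(white_frac) * stats::rnorm(n) + sqrt(1 - white_frac) * ar
}

#' Derive a stream-specific 32-bit seed from a base seed
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  offsets <- c(trials = 101L, grc = 211L, cf = 307L, lick = 401L,
               noise = 503L, folds = 601L, control = 701L, ltp = 809L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' Indices of time axis samples falling in a closed window
#' @keywords internal
#' @noRd
window_idx <- function(time_s, window) {
  which(time_s >= window[1] & time_s <= window[2])
}

#' Mean of a trace over a time window (error if empty)
#' @keywords internal
#' @noRd
window_mean <- function(time_s, x, window) {
  idx <- window_idx(time_s, window)
  if (length(idx) == 0L) stop("window [", window[1], ", ", window[2],
                              "] contains no samples")
  mean(x[idx])
}

#' Check a length-2 increasing numeric window
#' @keywords internal
#' @noRd
check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || !all(is.finite(window)) ||
      window[1] >= window[2]) {
    stop(name, " must be a finite, increasing length-2 numeric vector")
  }
  invisible(window)
}
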