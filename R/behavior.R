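#' Detect forelimb reaches from manipulandum position
#'
#' Segments the y-position stream into movement episodes and, for each
#' episode whose extent exceeds 4 mm, identifies: reach **end** as the first
#' time y comes within 0.5 mm of the episode maximum; reach **midpoint** as
#' the first time y exceeds 4 mm; and reach **start** as the latest time
#' before the midpoint at which the 100-ms-smoothed speed falls below
#' 15 mm/s. Reaches with extent > 7 mm are flagged `included` for analysis.
#'
#' @param y y-position in mm, uniformly sampled.
#' @param fs sampling rate, Hz (default 200).
#' @param min_extent_mm inclusion threshold (default 7).
#' @return data.frame with one row per detected reach: `start_s`, `mid_s`,
#'   `end_s`, `max_extent_mm`, `included`. Zero rows if the position never
#'   exceeds 4 mm.
#' @examples
#' t <- seq(0, 3, by = 1 / 200)
#' y <- pmin(8, pmax(0, (t - 1) * 20))
#' detect_reaches(y, 200)
#' @export
detect_reaches <- function(y, fs = 200, min_extent_mm = 7) {
  n <- length(y)
  tt <- (seq_len(n) - 1) / fs
  # 100-ms boxcar-smoothed speed from central differences
  vel <- c(0, (y[-(1:2)] - y[1:(n - 2)]) * fs / 2, 0)
  w <- round(0.1 * fs)
  if (w %% 2 == 0) w <- w + 1L
  speed <- moving_stat(abs(vel), w, mean, stride = 1L)

  above <- y > 4
  if (!any(above)) {
    return(data.frame(start_s = numeric(0), mid_s = numeric(0),
                      end_s = numeric(0), max_extent_mm = numeric(0),
                      included = logical(0)))
  }
  # movement episodes: contiguous runs above 1 mm containing a >4 mm crossing
  r <- rle(y > 1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    if (!any(y[seg] > 4)) next
    ymax <- max(y[seg])
    end_i <- seg[which(y[seg] >= ymax - 0.5)[1]]
    mid_i <- seg[which(y[seg] > 4)[1]]
    pre <- which(tt < tt[mid_i] & speed < 15)
    start_i <- if (length(pre)) max(pre) else seg[1]
    out[[length(out) + 1L]] <- data.frame(
      start_s = tt[start_i], mid_s = tt[mid_i], end_s = tt[end_i],
      max_extent_mm = ymax, included = ymax > min_extent_mm)
  }
  if (!length(out)) {
    return(data.frame(start_s = numeric(0), mid_s = numeric(0),
                      end_s = numeric(0), max_extent_mm = numeric(0),
                      included = logical(0)))
  }
  do.call(rbind, out)
}

#' Assemble the trial table from reaches and reward pulses
#'
#' Matches each included reach to the first solenoid pulse within
#' `delay_s + tol_s` of its end; unmatched reaches become omission trials
#' whose `reward_time_s` is the expected time (reach end + delay). Reward
#' pulses with no matching reach are warning-logged orphans.
#'
#' @param reaches data.frame from [detect_reaches()].
#' @param reward_pulse_times onset times of solenoid pulses, seconds.
#' @param delay_s nominal reach-end-to-reward delay, seconds.
#' @param tol_s matching tolerance, seconds (default 0.3).
#' @return data.frame: `trial`, `reach_start_s`, `reach_mid_s`,
#'   `reach_end_s`, `reward_time_s`, `omission`, `included`,
#'   `max_extent_mm`; one row per included reach, in time order.
#' @export
build_trial_table <- function(reaches, reward_pulse_times, delay_s,
                              tol_s = 0.3) {
  inc <- reaches[reaches$included, , drop = FALSE]
  inc <- inc[order(inc$end_s), , drop = FALSE]
  used <- rep(FALSE, length(reward_pulse_times))
  rows <- vector("list", nrow(inc))
  for (j in seq_len(nrow(inc))) {
    expected <- inc$end_s[j] + delay_s
    cand <- which(!used & abs(reward_pulse_times - expected) <= tol_s)
    if (length(cand)) {
      i <- cand[which.min(abs(reward_pulse_times[cand] - expected))]
      used[i] <- TRUE
      rows[[j]] <- data.frame(reward_time_s = reward_pulse_times[i],
                              omission = FALSE)
    } else {
      rows[[j]] <- data.frame(reward_time_s = expected, omission = TRUE)
    }
  }
  if (any(!used)) {
    warning(sum(!used), " reward pulse(s) had no matching reach (orphans at ",
            paste(signif(reward_pulse_times[!used], 5), collapse = ", "), ")")
  }
  res <- cbind(trial = seq_len(nrow(inc)),
               inc[, c("start_s", "mid_s", "end_s")],
               do.call(rbind, rows),
               included = TRUE, max_extent_mm = inc$max_extent_mm)
  names(res)[2:4] <- c("reach_start_s", "reach_mid_s", "reach_end_s")
  rownames(res) <- NULL
  res
}

#' Flag trials with a stuck lick sensor
#'
#' A trial is invalid iff the binary sensor is high for more than 90% of any
#' continuous 1.5-s block within the trial span (capacitive sensors can get
#' stuck in the on state).
#'
#' @param lick binary sensor stream.
#' @param fs sampling rate, Hz.
#' @param trial_windows two-column matrix (or data.frame) of trial start/end
#'   times in seconds.
#' @param block_s,max_duty stuck-block length and duty-cycle threshold.
#' @return Logical vector, `TRUE` = valid trial.
#' @export
lick_validity_mask <- function(lick, fs, trial_windows, block_s = 1.5,
                               max_duty = 0.9) {
  trial_windows <- as.matrix(trial_windows)
  n <- length(lick)
  w <- round(block_s * fs)
  cs <- c(0, cumsum(lick))
  duty <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w  # block starting at i
  vapply(seq_len(nrow(trial_windows)), function(j) {
    i0 <- max(1L, floor(trial_windows[j, 1] * fs) + 1L)
    i1 <- min(n, ceiling(trial_windows[j, 2] * fs) + 1L)
    lo <- min(i0, n - w + 1L)
    hi <- min(i1 - w + 1L, n - w + 1L)
    if (hi < lo) return(TRUE)
    !any(duty[lo:hi] > max_duty)
  }, logical(1))
}

#' Smooth lick-sensor onsets into a rate trace
#'
#' Lick onsets are 0-to-1 transitions of the raw binary contact trace; each
#' onset contributes a unit-area Gaussian kernel (FWHM `kernel_s`), so the
#' integral of the rate equals the onset count.
#'
#' @param lick binary sensor stream.
#' @param fs sampling rate, Hz.
#' @param kernel_s smoothing kernel FWHM, seconds (default 0.15).
#' @return Rate trace in licks/s with attribute `n_onsets`.
#' @export
lick_rate_trace <- function(lick, fs, kernel_s = 0.15) {
  n <- length(lick)
  onsets <- which(diff(c(0, lick)) == 1)
  rate <- kernel_rate(onsets, n, gaussian_kernel(kernel_s, 1 / fs), 1 / fs)
  attr(rate, "n_onsets") <- length(onsets)
  rate
}

#' Early-vs-late delay lick preference
#'
#' `(late - early) / (late + early)` over mean reward-aligned lick rates in
#' the early `[-0.8, -0.6]` s and late `[-0.2, 0]` s delay windows. Positive
#' values mean licking concentrated just before reward (expert-like).
#'
#' @param time_s reward-aligned time axis, seconds.
#' @param rate lick rate: vector, or trials x time matrix (averaged).
#' @param early,late window bounds.
#' @return List with `preference` (NA with `defined = FALSE` when both
#'   windows are zero), `early`, `late`, `defined`.
#' @export
lick_preference <- function(time_s, rate, early = c(-0.8, -0.6),
                            late = c(-0.2, 0)) {
  if (is.matrix(rate)) rate <- colMeans(rate)
  e <- window_mean(time_s, rate, early)
  l <- window_mean(time_s, rate, late)
  if (e + l <= 0) {
    return(list(preference = NA_real_, early = e, late = l, defined = FALSE))
  }
  list(preference = (l - e) / (l + e), early = e, late = l, defined = TRUE)
}

#' Per-trial lick off-time after reward
#'
#' Finds the peak lick rate over the `[-0.25, 0.5]` s peri-reward window and
#' returns the last time (up to `max_s`) at which the rate still exceeds 70%
#' of that peak. If the rate never falls below 50% of the peak within
#' `[0, max_s]`, licking never terminated and the off-time is defined as 0.
#'
#' @param time_s reward-aligned time axis.
#' @param rate single-trial lick rate over that axis.
#' @param peak_window window for the reference peak.
#' @param frac_off off-time threshold as a fraction of peak (default 0.7).
#' @param frac_never "never fell" threshold (default 0.5).
#' @param max_s latest off-time considered (default 2).
#' @return List with `off_time_s` and `defined` (`FALSE` when there are no
#'   licks in the peak window).
#' @export
lick_offtime <- function(time_s, rate, peak_window = c(-0.25, 0.5),
                         frac_off = 0.7, frac_never = 0.5, max_s = 2) {
  peak <- max(rate[window_idx(time_s, peak_window)])
  if (!is.finite(peak) || peak <= 0) {
    return(list(off_time_s = NA_real_, defined = FALSE))
  }
  post <- window_idx(time_s, c(0, max_s))
  if (!any(rate[post] < frac_never * peak)) {
    return(list(off_time_s = 0, defined = TRUE))
  }
  span <- window_idx(time_s, c(peak_window[1], max_s))
  above <- span[rate[span] > frac_off * peak]
  off <- if (length(above)) max(time_s[above]) else 0
  list(off_time_s = off, defined = TRUE)
}
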