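#' Build a trial-aligned tensor from a trace matrix
#'
#' Samples each cell's trace onto a relative time grid around a per-trial
#' alignment event by nearest-frame lookup. Alignment modes: `"reward"`
#' (t = 0 at reward/expected-reward), `"movement"` (t = 0 at the reach
#' midpoint), or `"concatenated"`, which joins movement-aligned and
#' reward-aligned segments on a reward-relative axis such that the movement
#' midpoint uniformly occurs at `-delay_s` (the join is halfway through the
#' delay, where the two alignments agree best on stereotyped trials).
#'
#' @param traces cells x frames matrix (z-scores or events/s).
#' @param frame_times frame clock, seconds.
#' @param trial_table data.frame with `reach_mid_s`, `reward_time_s`,
#'   `omission` (from [build_trial_table()] or a synthetic session).
#' @param align `"reward"`, `"movement"` or `"concatenated"`.
#' @param window length-2 relative time window, seconds.
#' @param subset `"all"`, `"rewarded"` or `"omission"`.
#' @param delay_s delay length; required for `"concatenated"`.
#' @return An `aligned_tensor`: 3-d array cells x time x trials with
#'   attributes `time_s`, `alignment`, `trial_ids`. Trials whose window
#'   exceeds the session bounds are dropped with a message.
#' @examples
#' ses <- simulate_session(synth_config(n_grc = 8, n_cf = 3, n_trials = 6,
#'                                      seed = 5))
#' tens <- align_to_trials(ses$grc$z, ses$frame_times_s, ses$trials,
#'                         "reward", c(-1.5, 0.5))
#' dim(tens)
#' @export
align_to_trials <- function(traces, frame_times, trial_table,
                            align = c("reward", "movement", "concatenated"),
                            window = c(-1.5, 0.5),
                            subset = c("all", "rewarded", "omission"),
                            delay_s = NULL) {
  align <- match.arg(align)
  subset <- match.arg(subset)
  check_window(window)
  stopifnot(is.matrix(traces), ncol(traces) == length(frame_times))
  tb <- trial_table
  if (subset == "rewarded") tb <- tb[!tb$omission, , drop = FALSE]
  if (subset == "omission") tb <- tb[tb$omission, , drop = FALSE]
  if (nrow(tb) == 0L) stop("no trials in requested subset")
  if (align == "concatenated" && is.null(delay_s))
    stop("'delay_s' is required for concatenated alignment")

  dt <- 1 / round(1 / median(diff(frame_times)), 6)
  rel <- seq(window[1], window[2], by = dt)
  nt <- length(rel)

  event_times <- switch(align,
    reward = tb$reward_time_s,
    movement = tb$reach_mid_s,
    concatenated = tb$reward_time_s)

  keep <- logical(nrow(tb))
  slices <- vector("list", nrow(tb))
  for (j in seq_len(nrow(tb))) {
    if (align == "concatenated") {
      # movement-midpoint alignment for the first half of the delay,
      # reward alignment thereafter; axis is reward-relative
      pre <- rel <= -delay_s / 2
      abs_t <- ifelse(pre, tb$reach_mid_s[j] + (rel + delay_s),
                      tb$reward_time_s[j] + rel)
    } else {
      abs_t <- event_times[j] + rel
    }
    if (min(abs_t) < frame_times[1] - dt / 2 ||
        max(abs_t) > frame_times[length(frame_times)] + dt / 2) {
      keep[j] <- FALSE
      next
    }
    idx <- pmin(length(frame_times),
                pmax(1L, round((abs_t - frame_times[1]) / dt) + 1L))
    slices[[j]] <- traces[, idx, drop = FALSE]
    keep[j] <- TRUE
  }
  if (!all(keep))
    message(sum(!keep), " trial(s) dropped: window exceeds session bounds")
  if (!any(keep)) stop("no trials fit in the session bounds")
  arr <- array(NA_real_, dim = c(nrow(traces), nt, sum(keep)))
  kk <- 0L
  for (j in which(keep)) {
    kk <- kk + 1L
    arr[, , kk] <- slices[[j]]
  }
  structure(arr, time_s = rel, alignment = align,
            trial_ids = tb$trial[keep], class = c("aligned_tensor", "array"))
}

#' Time axis of an aligned tensor
#' @param x an `aligned_tensor`.
#' @export
tensor_time <- function(x) attr(x, "time_s")

#' Trial-average matrix (cells x time) of an aligned tensor
#' @param x an `aligned_tensor`.
#' @export
tensor_trial_average <- function(x) {
  apply(unclass(x), c(1, 2), mean)
}
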