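#' Flag cells modulated in a window relative to baseline
#'
#' A cell is flagged iff the across-trial paired test between its per-trial
#' means in `window` and `baseline_window` gives p < `p_thresh` AND the mean
#' difference exceeds `magnitude` in absolute value (z-scores). The test is a
#' two-sided Wilcoxon signed-rank on the per-trial window means.
#'
#' @param tensor an `aligned_tensor` (z-scores or rates).
#' @param window,baseline_window length-2 windows on the tensor's time axis.
#' @param p_thresh,magnitude significance and magnitude criteria
#'   (defaults 0.05 and 0.2).
#' @return data.frame per cell: `modulated`, `delta` (mean difference),
#'   `p`, and `sign`.
#' @export
classify_modulated <- function(tensor, window, baseline_window,
                               p_thresh = 0.05, magnitude = 0.2) {
  tt <- tensor_time(tensor)
  n_trials <- dim(tensor)[3]
  if (n_trials < 2L) stop("at least 2 trials are required")
  wi <- window_idx(tt, window); bi <- window_idx(tt, baseline_window)
  if (!length(wi) || !length(bi)) stop("window outside tensor time axis")
  res <- lapply(seq_len(dim(tensor)[1]), function(ci) {
    wv <- colMeans(matrix(tensor[ci, wi, ], length(wi), n_trials))
    bv <- colMeans(matrix(tensor[ci, bi, ], length(bi), n_trials))
    d <- wv - bv
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(wv, bv, paired = TRUE)$p.value)
    data.frame(modulated = is.finite(p) && p < p_thresh &&
                 abs(mean(d)) > magnitude,
               delta = mean(d), p = p, sign = sign(mean(d)))
  })
  out <- do.call(rbind, res)
  out$cell <- seq_len(nrow(out))
  out[, c("cell", "modulated", "delta", "p", "sign")]
}

#' Flag anticipatory (reward-expectation) granule cells
#'
#' A GrC is anticipatory iff its trial-average activity in the late-delay
#' window `[-0.3, -0.03]` s exceeds the averages in both flanking windows —
#' early delay/pre-movement `[-1.3, -1]` s and post-reward `[0.3, 0.5]` s —
#' by more than `margin` z-scores.
#'
#' @param tensor reward-aligned `aligned_tensor` spanning at least
#'   `[-1.3, 0.5]` s.
#' @param window,flank_pre,flank_post comparison windows.
#' @param margin elevation criterion, z-scores (default 0.1).
#' @return data.frame per cell: `anticipatory`, `late_delay`, `pre`, `post`.
#' @export
classify_anticipatory_grcs <- function(tensor, window = c(-0.3, -0.03),
                                       flank_pre = c(-1.3, -1),
                                       flank_post = c(0.3, 0.5),
                                       margin = 0.1) {
  tt <- tensor_time(tensor)
  if (min(tt) > flank_pre[1] || max(tt) < flank_post[2])
    stop("tensor span insufficient: need at least [",
         flank_pre[1], ", ", flank_post[2], "] s")
  avg <- tensor_trial_average(tensor)
  late <- rowMeans(avg[, window_idx(tt, window), drop = FALSE])
  pre <- rowMeans(avg[, window_idx(tt, flank_pre), drop = FALSE])
  post <- rowMeans(avg[, window_idx(tt, flank_post), drop = FALSE])
  data.frame(cell = seq_len(nrow(avg)),
             anticipatory = late - pre > margin & late - post > margin,
             late_delay = late, pre = pre, post = post)
}

#' Flag reward-spiking climbing fibers
#'
#' A CF is reward-responsive iff its trial-average rate in `[0, 0.2]` s
#' after reward exceeds `margin` (in the tensor's units) and exceeds the
#' pre-reward `[-0.3, -0.03]` s rate by more than `margin`.
#'
#' @param tensor reward-aligned CF rate `aligned_tensor`.
#' @param window,pre_window comparison windows.
#' @param margin elevation criterion in the tensor's units (default 0.1).
#' @return data.frame per cell: `reward_cf`, `post`, `pre`.
#' @export
classify_reward_cfs <- function(tensor, window = c(0, 0.2),
                                pre_window = c(-0.3, -0.03), margin = 0.1) {
  tt <- tensor_time(tensor)
  if (min(tt) > pre_window[1] || max(tt) < window[2])
    stop("tensor span insufficient for reward-CF classification")
  avg <- tensor_trial_average(tensor)
  post <- rowMeans(avg[, window_idx(tt, window), drop = FALSE])
  pre <- rowMeans(avg[, window_idx(tt, pre_window), drop = FALSE])
  data.frame(cell = seq_len(nrow(avg)),
             reward_cf = post > margin & post - pre > margin,
             post = post, pre = pre)
}

#' Anticipation off-time of a single-trial trace
#'
#' Time after reward at which anticipatory fluorescence terminates: the
#' first post-reward time the trace falls below `frac` of its peak over the
#' late-delay `[-0.5, 0]` s window.
#'
#' @param time_s reward-aligned time axis.
#' @param trace single-trial (or trial-averaged) trace.
#' @param peak_window window defining the anticipation peak.
#' @param frac termination threshold as a fraction of peak (default 0.5).
#' @return List with `off_time_s` and `defined` (`FALSE` for flat or
#'   non-positive peaks, or when the trace never falls below threshold).
#' @export
anticipation_offtime <- function(time_s, trace, peak_window = c(-0.5, 0),
                                 frac = 0.5) {
  peak <- max(trace[window_idx(time_s, peak_window)])
  if (!is.finite(peak) || peak <= 0)
    return(list(off_time_s = NA_real_, defined = FALSE))
  post <- which(time_s >= 0)
  below <- post[trace[post] < frac * peak]
  if (!length(below)) return(list(off_time_s = NA_real_, defined = FALSE))
  list(off_time_s = time_s[min(below)], defined = TRUE)
}

#' Onset time of population CF spiking after reward (or omission)
#'
#' First time at or after reward at which the across-cell average rate rises
#' above the `pct` quantile of its values within the reward-response window
#' `[0, 0.2]` s.
#'
#' @param time_s reward-aligned time axis.
#' @param avg_rate across-cell average rate for one trial.
#' @param response_window window defining the reward response.
#' @param pct reference quantile (default 0.2).
#' @param search_max_s latest onset considered (default 1.5 s).
#' @param threshold absolute rate threshold. Defaults to the `pct` quantile
#'   of this trial's own reward-response window; on omission trials (no
#'   reward response) pass a threshold derived from the rewarded trials'
#'   reward response instead.
#' @return List with `onset_s` and `defined`.
#' @export
cf_onset_time <- function(time_s, avg_rate, response_window = c(0, 0.2),
                          pct = 0.2, search_max_s = 1.5, threshold = NULL) {
  thr <- if (is.null(threshold)) {
    quantile(avg_rate[window_idx(time_s, response_window)], pct,
             names = FALSE)
  } else threshold
  if (!is.finite(thr) || max(avg_rate[time_s >= 0], na.rm = TRUE) <= 0)
    return(list(onset_s = NA_real_, defined = FALSE))
  post <- window_idx(time_s, c(0, search_max_s))
  hit <- post[avg_rate[post] > thr]
  if (!length(hit)) return(list(onset_s = NA_real_, defined = FALSE))
  list(onset_s = time_s[min(hit)], defined = TRUE)
}

#' Anticipatory center time of a GrC
#'
#' Center of a cell's delay activity: either the activity-weighted centroid
#' of the rectified (above-zero) trial-average within the delay window
#' (default), or the mean of timepoints with activity elevated above
#' `margin` ("elevated-timepoint center").
#'
#' @param time_s reward-aligned time axis.
#' @param trace trial-averaged trace for one cell.
#' @param window delay window, e.g. `c(-1.1, 0)`.
#' @param method `"rectified_centroid"` or `"elevated_center"`.
#' @param margin elevation margin for `"elevated_center"` (default 0.1).
#' @return Center time in seconds (within `window`), or NA if the cell has
#'   no above-threshold activity in the window.
#' @export
anticipatory_center_time <- function(time_s, trace, window,
                                     method = c("rectified_centroid",
                                                "elevated_center"),
                                     margin = 0.1) {
  method <- match.arg(method)
  check_window(window)
  idx <- window_idx(time_s, window)
  v <- trace[idx]; tt <- time_s[idx]
  if (method == "rectified_centroid") {
    w <- pmax(v, 0)
    if (sum(w) <= 0) return(NA_real_)
    sum(tt * w) / sum(w)
  } else {
    el <- v > margin
    if (!any(el)) return(NA_real_)
    mean(tt[el])
  }
}

#' Duration of elevated activity after movement
#'
#' Total time within the movement-aligned window (default `[0, 2]` s) during
#' which the trial-average exceeds the pre-movement baseline (mean over
#' `[-1, 0]` s) by more than `margin` z-scores.
#'
#' @param time_s movement-aligned time axis.
#' @param trace trial-averaged trace for one cell.
#' @param window activity window (default `c(0, 2)`).
#' @param baseline_window pre-movement baseline window (default `c(-1, 0)`).
#' @param margin elevation margin, z-scores (default 0.1).
#' @return Duration in seconds.
#' @export
elevated_duration <- function(time_s, trace, window = c(0, 2),
                              baseline_window = c(-1, 0), margin = 0.1) {
  base <- window_mean(time_s, trace, baseline_window)
  idx <- window_idx(time_s, window)
  dt <- median(diff(time_s))
  sum(trace[idx] > base + margin) * dt
}
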