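#' Parameters of the CF-driven plasticity simulation
#'
#' Defaults implement the reward-spike LTD rule: CF spikes within
#' `[0, 0.25]` s of reward act as teaching events; each event tabulates the
#' GrC's mean activity over the eligibility window `[-0.150, -0.025]` s
#' preceding the spike; event magnitudes are bounded to (0, 1) by a logistic
#' with per-cell scale s = 95th-percentile fluorescence; CFs are included
#' iff their trial-averaged activity over `[0, 0.25]` s exceeds
#' `[-0.3, -0.025]` s; LTP events (optional extension) occur at the bottom
#' 0.5% of timepoints by CF firing rate.
#'
#' @param reward_spike_window_s CF teaching-spike window relative to reward.
#' @param eligibility_window_s GrC tabulation window relative to the CF
#'   spike (strictly pre-spike).
#' @param cf_post_window_s,cf_pre_window_s CF inclusion comparison windows.
#' @param logistic_scale_percentile percentile of each GrC's trace defining
#'   the logistic scale s (default 95).
#' @param rectify rectify eligibility activity at zero before the logistic
#'   (default TRUE; only above-baseline activity drives LTD).
#' @param ltp_rate_quantile quantile of CF rate timepoints treated as LTP
#'   events (default 0.005, the bottom 0.5%).
#' @param connection_prob GrC-to-PkC connection probability; 1 (default)
#'   means all-to-all, the simplification appropriate to small imaging
#'   fields.
#' @return A list of class `plasticity_params`.
#' @export
plasticity_params <- function(reward_spike_window_s = c(0, 0.25),
                              eligibility_window_s = c(-0.150, -0.025),
                              cf_post_window_s = c(0, 0.25),
                              cf_pre_window_s = c(-0.3, -0.025),
                              logistic_scale_percentile = 95,
                              rectify = TRUE,
                              ltp_rate_quantile = 0.005,
                              connection_prob = 1) {
  check_window(reward_spike_window_s, "reward_spike_window_s")
  check_window(eligibility_window_s, "eligibility_window_s")
  if (eligibility_window_s[2] >= 0)
    stop("eligibility window must be strictly pre-spike")
  stopifnot(logistic_scale_percentile > 0, logistic_scale_percentile < 100,
            ltp_rate_quantile > 0, ltp_rate_quantile < 1,
            connection_prob > 0, connection_prob <= 1)
  out <- list(reward_spike_window_s = reward_spike_window_s,
              eligibility_window_s = eligibility_window_s,
              cf_post_window_s = cf_post_window_s,
              cf_pre_window_s = cf_pre_window_s,
              logistic_scale_percentile = logistic_scale_percentile,
              rectify = rectify, ltp_rate_quantile = ltp_rate_quantile,
              connection_prob = connection_prob)
  class(out) <- "plasticity_params"
  out
}

#' Select CFs with detectable reward-evoked spiking
#'
#' A CF is included as a teaching signal iff its trial-averaged rate over
#' the post-reward window exceeds the pre-reward window.
#'
#' @param cf_rate_tensor reward-aligned CF rate `aligned_tensor`.
#' @param params a [plasticity_params()].
#' @return Logical vector, one element per CF.
#' @export
select_included_cfs <- function(cf_rate_tensor, params = plasticity_params()) {
  tt <- tensor_time(cf_rate_tensor)
  avg <- tensor_trial_average(cf_rate_tensor)
  post <- rowMeans(avg[, window_idx(tt, params$cf_post_window_s), drop = FALSE])
  pre <- rowMeans(avg[, window_idx(tt, params$cf_pre_window_s), drop = FALSE])
  post > pre
}

#' Extract per-trial CF reward spikes
#'
#' Keeps, for each CF and each rewarded (non-omission) trial, the spike
#' times falling within the reward-spike window, expressed relative to
#' reward.
#'
#' @param event_trains list of per-CF absolute spike times, seconds.
#' @param trial_table data.frame with `reward_time_s` and `omission`.
#' @param params a [plasticity_params()].
#' @param include_omission include omission trials (default FALSE; withheld
#'   reward evokes no teaching spike, and late omission spiking is not a
#'   reward event).
#' @return List (per CF) of lists (per trial, names = trial index) of
#'   reward-relative spike times.
#' @export
reward_spike_events <- function(event_trains, trial_table,
                                params = plasticity_params(),
                                include_omission = FALSE) {
  tb <- trial_table
  if (!include_omission) tb <- tb[!tb$omission, , drop = FALSE]
  win <- params$reward_spike_window_s
  lapply(event_trains, function(sp) {
    per_trial <- lapply(seq_len(nrow(tb)), function(j) {
      rel <- sp - tb$reward_time_s[j]
      rel[rel >= win[1] & rel <= win[2]]
    })
    names(per_trial) <- tb$trial
    per_trial
  })
}

#' Logistic-bounded plasticity event magnitude
#'
#' Maps eligibility-window GrC activity F to a bounded LTD/LTP event
#' magnitude `1 / (1 + exp(-F / s))`, optionally rectifying F at zero first
#' (so sub-baseline activity contributes the logistic floor of 0.5).
#' Monotone nondecreasing in F.
#'
#' @param F mean GrC activity in the eligibility window (z-scores); vector.
#' @param s per-cell logistic scale (positive); recycled against `F`.
#' @param rectify rectify F at zero (default TRUE).
#' @return Magnitudes in (0, 1); NA where `s <= 0` (degenerate cells).
#' @examples
#' plasticity_event_magnitude(0, 1)            # 0.5
#' plasticity_event_magnitude(1, 1)            # 1/(1+exp(-1))
#' @export
plasticity_event_magnitude <- function(F, s, rectify = TRUE) {
  s <- rep_len(s, length(F))
  if (rectify) F <- pmax(F, 0)
  out <- 1 / (1 + exp(-F / s))
  out[s <= 0] <- NA_real_
  out
}

#' Per-cell logistic scale from the fluorescence distribution
#'
#' @param traces cells x frames (or cells x time x trials) array of z-scored
#'   GrC activity.
#' @param percentile scale percentile (default 95).
#' @return Numeric vector of per-cell scales.
#' @export
logistic_scale <- function(traces, percentile = 95) {
  m <- if (length(dim(traces)) == 3L) {
    matrix(traces, dim(traces)[1], prod(dim(traces)[2:3]))
  } else traces
  apply(m, 1, quantile, probs = percentile / 100, names = FALSE)
}

# Pool (trial, spike) teaching events of one CF into per-GrC sums & counts.
# Returns list(sum = n_grc vector of magnitude sums, n = event count).
ltd_event_sums <- function(grc_tensor, spikes_per_trial, s, params) {
  tt <- tensor_time(grc_tensor)
  ew <- params$eligibility_window_s
  n_grc <- dim(grc_tensor)[1]
  trial_ids <- attr(grc_tensor, "trial_ids")
  sums <- numeric(n_grc)
  n_ev <- 0L
  for (tn in names(spikes_per_trial)) {
    k <- match(as.integer(tn), trial_ids)
    if (is.na(k)) next
    for (sp in spikes_per_trial[[tn]]) {
      idx <- window_idx(tt, sp + ew)
      if (!length(idx)) next
      F <- rowMeans(grc_tensor[, idx, k, drop = FALSE], dims = 1)
      mag <- plasticity_event_magnitude(F, s, params$rectify)
      sums <- sums + ifelse(is.na(mag), 0, mag)
      n_ev <- n_ev + 1L
    }
  }
  list(sum = sums, n = n_ev)
}

# Normalization chain shared by every provenance: unit-sum each per-PkC
# vector, subtract its mean, average across PkCs, negate (sign of LTD).
make_weight_set <- function(per_cf_raw, provenance, params,
                            grc_ltd_magnitude = NULL, readout_vector = NULL) {
  per_cf_raw <- as.matrix(per_cf_raw)
  rs <- rowSums(per_cf_raw)
  if (any(abs(rs) < 1e-12))
    stop("degenerate per-PkC weight vector: sum is zero, cannot unit-sum")
  unit <- sweep(per_cf_raw, 1, rs, `/`)
  centered <- unit - rowMeans(unit)
  session <- -colMeans(centered)
  out <- list(per_pkc = centered, session_vector = session,
              readout_vector = if (is.null(readout_vector)) session else readout_vector,
              grc_ltd_magnitude = grc_ltd_magnitude,
              provenance = provenance, params = params,
              n_pkc = nrow(per_cf_raw), n_grc = ncol(per_cf_raw))
  class(out) <- "weight_set"
  out
}

#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set> provenance=", x$provenance, ", ", x$n_pkc,
      " PkC(s) x ", x$n_grc, " GrCs; session vector mean ",
      signif(mean(x$session_vector), 3), "\n", sep = "")
  invisible(x)
}

#' Predicted GrC-to-PkC weights from reward-evoked CF LTD
#'
#' For each included CF (a proxy for its target PkC) and each GrC, averages
#' the logistic-bounded LTD event magnitudes over all pooled reward spikes
#' and trials, then normalizes each per-PkC vector to unit sum, subtracts
#' its mean, averages across PkCs and negates, so that GrCs most active just
#' before reward-evoked CF spikes receive the most negative readout weight.
#'
#' @param grc_tensor reward-aligned GrC `aligned_tensor` (rewarded trials);
#'   must cover the eligibility windows of all spikes.
#' @param cf_spikes output of [reward_spike_events()], restricted to
#'   included CFs.
#' @param params a [plasticity_params()].
#' @param logistic_s optional per-GrC logistic scale; computed from the
#'   tensor's fluorescence distribution by default. Cells with `s <= 0` are
#'   skipped with a message.
#' @return A `weight_set` with provenance `"true"`; `grc_ltd_magnitude`
#'   holds the pre-normalization per-GrC mean LTD magnitude (averaged over
#'   CFs).
#' @export
compute_session_weights <- function(grc_tensor, cf_spikes,
                                    params = plasticity_params(),
                                    logistic_s = NULL) {
  n_grc <- dim(grc_tensor)[1]
  if (is.null(logistic_s))
    logistic_s <- logistic_scale(unclass(grc_tensor),
                                 params$logistic_scale_percentile)
  if (any(logistic_s <= 0))
    message(sum(logistic_s <= 0),
            " GrC(s) with non-positive logistic scale skipped")
  per_cf <- matrix(NA_real_, length(cf_spikes), n_grc)
  kept <- logical(length(cf_spikes))
  for (c_i in seq_along(cf_spikes)) {
    ev <- ltd_event_sums(grc_tensor, cf_spikes[[c_i]], logistic_s, params)
    if (ev$n == 0L) next
    kept[c_i] <- TRUE
    per_cf[c_i, ] <- ev$sum / ev$n
  }
  if (!any(kept)) stop("no teaching signal: no included CF has reward spikes")
  per_cf <- per_cf[kept, , drop = FALSE]
  per_cf[!is.finite(per_cf)] <- 0  # degenerate cells carry no LTD
  make_weight_set(per_cf, "true", params,
                  grc_ltd_magnitude = colMeans(per_cf))
}

#' LTP-adjusted GrC-to-PkC weights
#'
#' Extends the LTD rule with opposing LTP: for each CF, timepoints in the
#' bottom `ltp_rate_quantile` of its firing-rate distribution (across
#' trials) are LTP events, tabulated over the same eligibility window. The
#' net per-(CF, GrC) tally is the LTD event-magnitude sum minus the LTP
#' event-magnitude sum, followed by the same normalization chain, so a CF
#' with no sub-threshold timepoints reduces exactly to the pure-LTD result.
#'
#' @param grc_tensor reward-aligned GrC `aligned_tensor`.
#' @param cf_rate_tensor reward-aligned rate tensor of the same CFs (same
#'   trials/time axis).
#' @param cf_spikes output of [reward_spike_events()] for the same CFs.
#' @param params a [plasticity_params()].
#' @param logistic_s optional per-GrC logistic scale.
#' @param seed seed for breaking rate ties (many timepoints share rate 0).
#' @return A `weight_set` with provenance `"ltp_adjusted"`.
#' @export
compute_ltp_adjusted_weights <- function(grc_tensor, cf_rate_tensor,
                                         cf_spikes,
                                         params = plasticity_params(),
                                         logistic_s = NULL, seed = 1L) {
  stopifnot(dim(cf_rate_tensor)[1] == length(cf_spikes))
  tt <- tensor_time(grc_tensor)
  ew <- params$eligibility_window_s
  n_grc <- dim(grc_tensor)[1]
  if (is.null(logistic_s))
    logistic_s <- logistic_scale(unclass(grc_tensor),
                                 params$logistic_scale_percentile)
  n_time <- dim(cf_rate_tensor)[2]
  n_trials <- dim(cf_rate_tensor)[3]
  set.seed(derive_seed(seed, "ltp"))
  tie_break <- runif(n_time * n_trials)
  n_ltp <- ceiling(params$ltp_rate_quantile * n_time * n_trials)

  per_cf <- matrix(NA_real_, length(cf_spikes), n_grc)
  kept <- logical(length(cf_spikes))
  for (c_i in seq_along(cf_spikes)) {
    ltd <- ltd_event_sums(grc_tensor, cf_spikes[[c_i]], logistic_s, params)
    rates <- as.vector(cf_rate_tensor[c_i, , ])
    ord <- order(rates, tie_break)[seq_len(n_ltp)]
    ltp_sum <- numeric(n_grc)
    n_ltp_used <- 0L
    for (pt in ord) {
      k <- ((pt - 1L) %/% n_time) + 1L
      fi <- ((pt - 1L) %% n_time) + 1L
      idx <- window_idx(tt, tt[fi] + ew)
      if (!length(idx)) next
      F <- rowMeans(grc_tensor[, idx, k, drop = FALSE], dims = 1)
      mag <- plasticity_event_magnitude(F, logistic_s, params$rectify)
      ltp_sum <- ltp_sum + ifelse(is.na(mag), 0, mag)
      n_ltp_used <- n_ltp_used + 1L
    }
    if (ltd$n == 0L && n_ltp_used == 0L) next
    kept[c_i] <- TRUE
    per_cf[c_i, ] <- ltd$sum - ltp_sum
  }
  if (!any(kept)) stop("no teaching signal: no plasticity events found")
  per_cf <- per_cf[kept, , drop = FALSE]
  per_cf[!is.finite(per_cf)] <- 0
  make_weight_set(per_cf, "ltp_adjusted", params)
}

#' Null-control weight sets
#'
#' Three controls for the LTD weight computation:
#' `"time_shuffled"` permutes the timepoints of every (GrC, trial) slice and
#' reruns the full LTD pipeline (each GrC keeps its per-trial value
#' distribution but loses its timing relative to CF spikes);
#' `"reordered"` randomly permutes the true session weight vector across
#' GrCs (each GrC gets a random weight from the true distribution);
#' `"uniform"` is the simple GrC average (equal weights; the mean-subtracted
#' session vector is identically zero and the readout uses the
#' pre-subtraction uniform average).
#'
#' @param grc_tensor reward-aligned GrC `aligned_tensor`.
#' @param cf_spikes output of [reward_spike_events()] (included CFs).
#' @param mode `"time_shuffled"`, `"reordered"` or `"uniform"`.
#' @param seed permutation seed.
#' @param params a [plasticity_params()].
#' @param true_weights optional precomputed `"true"` `weight_set` (avoids
#'   recomputation for `"reordered"`).
#' @param logistic_s optional per-GrC logistic scale, passed through to the
#'   LTD pipeline (time-point permutation leaves the fluorescence
#'   distribution, hence the scale, unchanged).
#' @return A `weight_set` with the control's provenance.
#' @export
control_weights <- function(grc_tensor, cf_spikes,
                            mode = c("time_shuffled", "reordered", "uniform"),
                            seed = 1L, params = plasticity_params(),
                            true_weights = NULL, logistic_s = NULL) {
  mode <- match.arg(mode)
  n_grc <- dim(grc_tensor)[1]
  if (mode == "uniform") {
    ws <- make_weight_set(matrix(1 / n_grc, 1, n_grc), "uniform", params,
                          readout_vector = rep(1 / n_grc, n_grc))
    return(ws)
  }
  set.seed(derive_seed(seed, "control"))
  if (mode == "reordered") {
    if (is.null(true_weights))
      true_weights <- compute_session_weights(grc_tensor, cf_spikes, params,
                                              logistic_s)
    perm <- sample.int(n_grc)
    ws <- true_weights
    ws$session_vector <- ws$session_vector[perm]
    ws$readout_vector <- ws$session_vector
    ws$per_pkc <- ws$per_pkc[, perm, drop = FALSE]
    ws$grc_ltd_magnitude <- ws$grc_ltd_magnitude[perm]
    ws$provenance <- "reordered"
    return(ws)
  }
  # time_shuffled: permute timepoints independently per (GrC, trial)
  shuf <- unclass(grc_tensor)
  n_time <- dim(shuf)[2]
  for (k in seq_len(dim(shuf)[3])) {
    for (ci in seq_len(n_grc)) {
      shuf[ci, , k] <- shuf[ci, sample.int(n_time), k]
    }
  }
  shuf <- structure(shuf, time_s = tensor_time(grc_tensor),
                    alignment = attr(grc_tensor, "alignment"),
                    trial_ids = attr(grc_tensor, "trial_ids"),
                    class = c("aligned_tensor", "array"))
  ws <- compute_session_weights(shuf, cf_spikes, params, logistic_s)
  ws$provenance <- "time_shuffled"
  ws
}
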