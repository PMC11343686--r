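# Shared synthetic fixtures (built once per test run) and independent
# oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

# A cached session keyed by its config; keeps the suite fast while letting
# multiple files share the same mid-sized expert session.
fixture_session <- function(key = "default", ...) {
  if (is.null(.fixture_env[[key]])) {
    args <- utils::modifyList(
      list(n_grc = 40, n_cf = 10, n_trials = 40, seed = 42), list(...))
    .fixture_env[[key]] <- simulate_session(do.call(synth_config, args))
  }
  .fixture_env[[key]]
}

# Reward-aligned tensor over the delay plus flanks.
reward_tensor <- function(ses, traces = ses$grc$z, subset = "rewarded",
                          pre = 0.6, post = 0.6) {
  align_to_trials(traces, ses$frame_times_s, ses$trials, "reward",
                  c(-ses$config$delay_s - pre, post), subset = subset)
}

# Smoothed rate matrix from the generator's true CF spike times.
true_cf_rates <- function(ses) {
  fs <- ses$config$frame_rate_hz
  do.call(rbind, lapply(ses$cf$events_true, function(ev)
    event_rate(ev, fs, length(ses$frame_times_s), 0.2, ses$frame_times_s)))
}

# Convenience: included-CF reward spikes + per-cell logistic scales.
session_teaching <- function(ses, params = plasticity_params()) {
  rates <- true_cf_rates(ses)
  cft <- reward_tensor(ses, traces = rates)
  inc <- select_included_cfs(cft, params)
  list(inc = inc,
       spikes = reward_spike_events(ses$cf$events_true[inc], ses$trials,
                                    params),
       rate_tensor = cft,
       s = logistic_scale(ses$grc$z, params$logistic_scale_percentile))
}

# ---- independent brute-force oracles (deliberately naive triple loops) ----

bf_logistic <- function(F, s, rectify = TRUE) {
  if (rectify) F <- max(F, 0)
  1 / (1 + exp(-F / s))
}

# Per-CF raw LTD tally: mean event magnitude per GrC, pooled over
# (trial, spike) events. Returns list(per_cf matrix, kept).
bf_per_cf_ltd <- function(tensor, spikes, s, elig = c(-0.150, -0.025),
                          rectify = TRUE) {
  tt <- attr(tensor, "time_s")
  ids <- attr(tensor, "trial_ids")
  n_grc <- dim(tensor)[1]
  per <- matrix(NA_real_, length(spikes), n_grc)
  kept <- logical(length(spikes))
  for (ci in seq_along(spikes)) {
    tot <- rep(0, n_grc); nev <- 0L
    for (tn in names(spikes[[ci]])) {
      k <- which(ids == as.integer(tn))
      if (!length(k)) next
      for (sp in spikes[[ci]][[tn]]) {
        sel <- which(tt >= sp + elig[1] & tt <= sp + elig[2])
        if (!length(sel)) next
        for (g in seq_len(n_grc)) {
          F <- mean(tensor[g, sel, k])
          tot[g] <- tot[g] + bf_logistic(F, s[g], rectify)
        }
        nev <- nev + 1L
      }
    }
    if (nev > 0L) { per[ci, ] <- tot / nev; kept[ci] <- TRUE }
  }
  list(per_cf = per[kept, , drop = FALSE], kept = kept)
}

bf_normalize <- function(per_cf) {
  u <- sweep(per_cf, 1, rowSums(per_cf), `/`)
  cen <- u - rowMeans(u)
  -colMeans(cen)
}

bf_session_weights <- function(tensor, spikes, s, elig = c(-0.150, -0.025),
                               rectify = TRUE) {
  bf_normalize(bf_per_cf_ltd(tensor, spikes, s, elig, rectify)$per_cf)
}

# LTP-adjusted oracle; assumes untied rate values so the bottom-quantile
# timepoint set is unambiguous.
bf_ltp_weights <- function(tensor, rate_tensor, spikes, s, q = 0.005,
                           elig = c(-0.150, -0.025), rectify = TRUE) {
  tt <- attr(tensor, "time_s")
  n_grc <- dim(tensor)[1]
  n_time <- dim(rate_tensor)[2]; n_tr <- dim(rate_tensor)[3]
  n_ltp <- ceiling(q * n_time * n_tr)
  per <- matrix(NA_real_, length(spikes), n_grc)
  kept <- logical(length(spikes))
  for (ci in seq_along(spikes)) {
    ltd <- bf_per_cf_ltd(tensor, spikes[ci], s, elig, rectify)
    ltd_sum <- if (nrow(ltd$per_cf)) {
      nev <- sum(lengths(spikes[[ci]]))
      ltd$per_cf[1, ] * nev
    } else rep(0, n_grc)
    rates <- as.vector(rate_tensor[ci, , ])
    ord <- order(rates)[seq_len(n_ltp)]
    ltp_sum <- rep(0, n_grc)
    for (pt in ord) {
      k <- ((pt - 1L) %/% n_time) + 1L
      fi <- ((pt - 1L) %% n_time) + 1L
      sel <- which(tt >= tt[fi] + elig[1] & tt <= tt[fi] + elig[2])
      if (!length(sel)) next
      for (g in seq_len(n_grc)) {
        ltp_sum[g] <- ltp_sum[g] + bf_logistic(mean(tensor[g, sel, k]),
                                               s[g], rectify)
      }
    }
    per[ci, ] <- ltd_sum - ltp_sum
    kept[ci] <- TRUE
  }
  bf_normalize(per[kept, , drop = FALSE])
}

# Tiny handcrafted tensor builder: cells x time x trials with a given time
# axis and trial ids, wrapped as an aligned_tensor.
make_tensor <- function(values, time_s, trial_ids = seq_len(dim(values)[3]),
                        alignment = "reward") {
  structure(values, time_s = time_s, alignment = alignment,
            trial_ids = trial_ids, class = c("aligned_tensor", "array"))
}
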