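#' Simulate a climbing-fiber (Purkinje-dendrite) population with ground truth
#'
#' Each CF fires spontaneous Poisson background spikes at `cf_baseline_hz`.
#' Reward-responsive cells additionally emit, with probability
#' `p_reward_spike` per rewarded trial, a spike within [0, 0.2] s of reward;
#' on omission trials the reward spike is absent and a late spike is placed
#' near the (delayed) anticipation off-time instead. A configurable fraction
#' of cells spike at movement, and another fraction has its background
#' partially suppressed during the delay. Dendritic fluorescence is the spike
#' train convolved with a single-exponential calcium kernel plus measurement
#' noise.
#'
#' @param config a [synth_config()].
#' @param trials a [simulate_trials()] result.
#' @return A list of class `synth_cf`:
#' \describe{
#'   \item{z}{cells x frames fluorescence matrix (z-score scale).}
#'   \item{raw}{cells x frames synthetic raw fluorescence.}
#'   \item{events_true}{list of per-cell sorted true spike times, seconds.}
#'   \item{frame_times_s}{frame clock.}
#'   \item{truth}{per-cell data.frame: `cell`, `reward_responsive`,
#'     `p_reward_spike`, `movement_responsive`, `suppressed_during_delay`.}
#' }
#' @examples
#' cfg <- synth_config(n_grc = 5, n_cf = 4, n_trials = 6, seed = 7)
#' cf <- simulate_cf_population(cfg, simulate_trials(cfg))
#' lengths(cf$events_true)
#' @export
simulate_cf_population <- function(config, trials) {
  stopifnot(inherits(config, "synth_config"), inherits(trials, "synth_trials"))
  if (config$cf_baseline_hz < 0) stop("'cf_baseline_hz' must be >= 0")
  set.seed(derive_seed(config$seed, "cf"))
  fs <- config$frame_rate_hz
  dtf <- 1 / fs
  ft <- seq(0, trials$duration_s, by = dtf)
  nf <- length(ft)
  n <- config$n_cf
  tb <- trials$trials
  delay <- config$delay_s

  reward_resp <- seq_len(n) %in% sample.int(n, round(config$frac_cf_reward * n))
  move_resp <- runif(n) < config$frac_cf_movement
  suppressed <- runif(n) < config$frac_cf_suppressed

  events <- vector("list", n)
  for (ci in seq_len(n)) {
    nb <- rpois(1, config$cf_baseline_hz * trials$duration_s)
    sp <- sort(runif(nb, 0, trials$duration_s))
    if (suppressed[ci] && length(sp)) {
      in_delay <- rep(FALSE, length(sp))
      for (j in seq_len(nrow(tb)))
        in_delay <- in_delay | (sp >= tb$reach_end_s[j] & sp < tb$reward_time_s[j])
      drop <- in_delay & runif(length(sp)) < 0.5
      sp <- sp[!drop]
    }
    if (move_resp[ci]) {
      hit <- runif(nrow(tb)) < 0.3
      sp <- c(sp, tb$reach_mid_s[hit] + runif(sum(hit), -0.05, 0.1))
    }
    if (reward_resp[ci]) {
      for (j in seq_len(nrow(tb))) {
        if (!tb$omission[j]) {
          if (runif(1) < config$p_reward_spike)
            sp <- c(sp, tb$reward_time_s[j] + runif(1, 0, 0.2))
        } else {
          if (runif(1) < 0.8 * config$p_reward_spike)
            sp <- c(sp, tb$reward_time_s[j] + runif(1, 0.3, 0.7))
        }
      }
    }
    sp <- sort(sp[sp >= 0 & sp <= trials$duration_s])
    if (length(sp) > 1L) sp <- sp[c(TRUE, diff(sp) > 1e-4)]
    events[[ci]] <- sp
  }

  z <- matrix(0, n, nf)
  for (ci in seq_len(n)) {
    impulses <- numeric(nf)
    sp <- events[[ci]]
    if (length(sp)) {
      fr <- pmin(nf, pmax(1L, round(sp / dtf) + 1L))
      amps <- runif(length(sp), 4, 6)
      for (k in seq_along(fr)) impulses[fr[k]] <- impulses[fr[k]] + amps[k]
    }
    z[ci, ] <- calcium_convolve(impulses, dtf, config$ca_tau_s, "peak") +
      config$noise_sigma * fluor_noise(nf, dtf, config$ca_tau_s,
                                       config$noise_white_frac)
  }

  bp <- config$bleach_params
  bleach <- bp$amps[1] * exp(-ft / bp$taus[1]) + bp$amps[2] * exp(-ft / bp$taus[2])
  raw <- sweep(bp$f0 + bp$gain * z, 2, bleach, `*`)

  truth <- data.frame(cell = seq_len(n), reward_responsive = reward_resp,
                      p_reward_spike = ifelse(reward_resp, config$p_reward_spike, 0),
                      movement_responsive = move_resp,
                      suppressed_during_delay = suppressed)
  out <- list(z = z, raw = raw, events_true = events, frame_times_s = ft,
              truth = truth)
  class(out) <- "synth_cf"
  out
}
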