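#' Configuration for a synthetic GrC-CF imaging session
#'
#' Bundles every parameter of the synthetic session generator. Defaults
#' describe an expert session on the 1.1-s-delay reaching task: a random 20%
#' of trials omit reward, roughly a third of GrCs carry anticipatory delay
#' activity, half of CFs spike at reward on a ~1 Hz spontaneous background,
#' and traces are sampled at 30 Hz with behavior streams at 200 Hz.
#'
#' @param n_grc,n_cf,n_trials counts of granule cells, climbing fibers
#'   (imaged Purkinje-cell dendrites), and included trials.
#' @param delay_s delay between reach end and reward, seconds (tasks use 1,
#'   1.1 or 2 s; any positive value is accepted).
#' @param basis_delay_s delay length the GrC temporal basis was learned for,
#'   seconds. Defaults to `delay_s`; set shorter than `delay_s` to emulate a
#'   population trained on a shorter delay and probed on longer trials (the
#'   1-s-expert-on-2-s-trials regime).
#' @param omission_frac fraction of trials with reward withheld, in [0, 1).
#' @param frame_rate_hz imaging frame rate (30 or 22.5 Hz in the recordings;
#'   any positive rate is accepted).
#' @param behav_rate_hz behavioral stream sampling rate, Hz.
#' @param frac_anticipatory fraction of GrCs with anticipatory delay ramps.
#' @param frac_grc_movement,frac_grc_reward fractions of GrCs with brief
#'   movement-locked / reward-consumption transients.
#' @param frac_cf_reward fraction of CFs emitting reward-evoked spikes.
#' @param frac_cf_movement fraction of CFs with movement-locked spiking.
#' @param frac_cf_suppressed fraction of CFs whose background spiking is
#'   partially suppressed during the delay.
#' @param p_reward_spike per-trial probability that a reward-responsive CF
#'   emits its reward spike.
#' @param cf_baseline_hz spontaneous CF spike rate, Hz.
#' @param ca_tau_s calcium indicator decay time constant, seconds.
#' @param noise_sigma fluorescence noise standard deviation, z-score units.
#' @param noise_white_frac fraction of noise variance that is white (the rest
#'   is AR(1)-correlated with `ca_tau_s`).
#' @param bleach_params list with `amps` and `taus` (each length 2) of the
#'   multiplicative double-exponential photobleaching envelope, plus scalar
#'   `f0` (baseline fluorescence) and `gain` (fluorescence units per z-score)
#'   for raw-trace synthesis.
#' @param drift_amp additive slow drift amplitude in units of `noise_sigma`.
#' @param expertise `"expert"` or `"novice"`. Novice sessions carry brief,
#'   early anticipatory transients instead of delay-spanning ramps, and
#'   early-delay rather than reward-ramping licking.
#' @param frac_short_reach fraction (of `n_trials`) of extra abortive reaches
#'   (< 7 mm) interleaved into the behavior stream, never rewarded.
#' @param seed integer seed; identical configs give bit-identical sessions.
#'
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_grc = 30, n_cf = 6, n_trials = 12, seed = 1)
#' cfg$delay_s
#' @export
synth_config <- function(n_grc = 150L, n_cf = 20L, n_trials = 100L,
                         delay_s = 1.1, basis_delay_s = NULL,
                         omission_frac = 0.2,
                         frame_rate_hz = 30, behav_rate_hz = 200,
                         frac_anticipatory = 0.34,
                         frac_grc_movement = 0.08, frac_grc_reward = 0.08,
                         frac_cf_reward = 0.5, frac_cf_movement = 0.22,
                         frac_cf_suppressed = 0.14,
                         p_reward_spike = 0.8, cf_baseline_hz = 1,
                         ca_tau_s = 0.15, noise_sigma = 1,
                         noise_white_frac = 0.2,
                         bleach_params = list(amps = c(0.3, 1.0),
                                              taus = c(120, 5000),
                                              f0 = 50, gain = 5),
                         drift_amp = 0.3,
                         expertise = c("expert", "novice"),
                         frac_short_reach = 0.1,
                         seed = 1L) {
  expertise <- match.arg(expertise)
  cfg <- list(n_grc = as.integer(n_grc), n_cf = as.integer(n_cf),
              n_trials = as.integer(n_trials), delay_s = delay_s,
              basis_delay_s = if (is.null(basis_delay_s)) delay_s else basis_delay_s,
              omission_frac = omission_frac,
              frame_rate_hz = frame_rate_hz, behav_rate_hz = behav_rate_hz,
              frac_anticipatory = frac_anticipatory,
              frac_grc_movement = frac_grc_movement,
              frac_grc_reward = frac_grc_reward,
              frac_cf_reward = frac_cf_reward,
              frac_cf_movement = frac_cf_movement,
              frac_cf_suppressed = frac_cf_suppressed,
              p_reward_spike = p_reward_spike,
              cf_baseline_hz = cf_baseline_hz,
              ca_tau_s = ca_tau_s, noise_sigma = noise_sigma,
              noise_white_frac = noise_white_frac,
              bleach_params = bleach_params, drift_amp = drift_amp,
              expertise = expertise, frac_short_reach = frac_short_reach,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  fracs <- c("omission_frac", "frac_anticipatory", "frac_grc_movement",
             "frac_grc_reward", "frac_cf_reward", "frac_cf_movement",
             "frac_cf_suppressed", "p_reward_spike", "noise_white_frac",
             "frac_short_reach")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("'", f, "' must be a fraction in [0, 1]")
  }
  if (cfg$omission_frac >= 1) stop("'omission_frac' must be < 1")
  if (cfg$delay_s <= 0) stop("'delay_s' must be > 0")
  if (cfg$basis_delay_s <= 0) stop("'basis_delay_s' must be > 0")
  if (cfg$frame_rate_hz <= 0) stop("'frame_rate_hz' must be > 0")
  if (cfg$behav_rate_hz <= 0) stop("'behav_rate_hz' must be > 0")
  if (cfg$n_trials < 1L) stop("'n_trials' must be >= 1")
  if (cfg$n_grc < 1L || cfg$n_cf < 1L) stop("cell counts must be >= 1")
  if (cfg$cf_baseline_hz < 0) stop("'cf_baseline_hz' must be >= 0")
  if (cfg$ca_tau_s <= 0) stop("'ca_tau_s' must be > 0")
  if (cfg$noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  bp <- cfg$bleach_params
  if (!is.list(bp) || !all(c("amps", "taus") %in% names(bp)) ||
      length(bp$amps) != 2L || length(bp$taus) != 2L)
    stop("'bleach_params' must list 2 'amps' and 2 'taus'")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$expertise, " session: ",
      x$n_grc, " GrCs, ", x$n_cf, " CFs, ", x$n_trials, " trials, ",
      x$delay_s, "-s delay (basis ", x$basis_delay_s, " s), ",
      round(100 * x$omission_frac), "% omissions, ",
      x$frame_rate_hz, " Hz, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
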