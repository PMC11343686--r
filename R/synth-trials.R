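#' Simulate self-initiated reach trials and 200 Hz behavior streams
#'
#' Generates the behavioral scaffold of a session: self-initiated forelimb
#' reaches to an 8 mm virtual wall separated by variable inter-trial gaps,
#' a solenoid reward pulse exactly `delay_s` after reach end on non-omission
#' trials, a seeded random `omission_frac` subset of omission trials, an
#' interleaved set of abortive (< 7 mm) reaches, and a capacitive lick-sensor
#' stream drawn from an inhomogeneous Poisson contact model whose rate
#' template depends on expertise (novice: licking concentrated early in the
#' delay; expert: ramping toward reward with a consummatory burst after it,
#' truncated after omission).
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_trials`:
#' \describe{
#'   \item{trials}{data.frame, one row per included trial: `trial`,
#'     `reach_start_s`, `reach_mid_s`, `reach_end_s`, `reward_time_s`
#'     (expected time on omission trials), `omission`, `included`,
#'     `max_extent_mm`.}
#'   \item{behavior}{data.frame at `behav_rate_hz`: `t`, `x`, `y` (mm),
#'     `reward` (solenoid logic level), `lick` (binary sensor contact).}
#'   \item{duration_s}{session length, seconds.}
#' }
#' @examples
#' tr <- simulate_trials(synth_config(n_trials = 5, seed = 3))
#' head(tr$trials)
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, "trials"))
  fs <- config$behav_rate_hz
  dt <- 1 / fs
  delay <- config$delay_s
  n_inc <- config$n_trials
  n_short <- round(config$frac_short_reach * n_inc)
  n_att <- n_inc + n_short
  is_short <- sample(c(rep(FALSE, n_inc), rep(TRUE, n_short)))

  gaps <- runif(n_att, 1.5, 3)
  rises <- runif(n_att, 0.35, 0.5)
  extents <- ifelse(is_short, runif(n_att, 4.5, 6.8), 8)
  omit <- rep(FALSE, n_inc)
  n_omit <- round(config$omission_frac * n_inc)
  if (n_omit > 0) omit[sample.int(n_inc, n_omit)] <- TRUE

  # lay out attempts sequentially
  onset <- numeric(n_att); att_end <- numeric(n_att)
  reach_end <- numeric(n_att); reach_mid <- rep(NA_real_, n_att)
  reward_t <- rep(NA_real_, n_att)
  cursor <- 2
  k_inc <- 0L
  inc_rows <- vector("list", n_inc)
  for (i in seq_len(n_att)) {
    onset[i] <- cursor + gaps[i]
    ext <- extents[i]; rise <- rises[i]
    reach_end[i] <- onset[i] + rise * (ext - 0.5) / ext
    if (ext > 4) reach_mid[i] <- onset[i] + rise * 4 / ext
    if (!is_short[i]) {
      k_inc <- k_inc + 1L
      reward_t[i] <- reach_end[i] + delay
      hold_end <- reward_t[i] + 1.5
      inc_rows[[k_inc]] <- data.frame(
        trial = k_inc,
        reach_start_s = onset[i], reach_mid_s = reach_mid[i],
        reach_end_s = reach_end[i], reward_time_s = reward_t[i],
        omission = omit[k_inc], included = TRUE, max_extent_mm = ext)
    } else {
      hold_end <- onset[i] + rise + 0.25
    }
    att_end[i] <- hold_end + 0.3  # arm return
    cursor <- att_end[i]
  }
  duration <- cursor + 2
  trials <- do.call(rbind, inc_rows)

  # position stream: linear rise, hold at extent, linear return
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  y <- numeric(n)
  for (i in seq_len(n_att)) {
    ext <- extents[i]; rise <- rises[i]
    hold_end <- att_end[i] - 0.3
    idx <- which(tt >= onset[i] & tt <= att_end[i])
    rel <- tt[idx] - onset[i]
    seg <- ifelse(rel <= rise, ext * rel / rise,
                  ifelse(tt[idx] <= hold_end, ext,
                         pmax(0, ext * (1 - (tt[idx] - hold_end) / 0.3))))
    y[idx] <- seg
  }
  y <- y + rnorm(n, sd = 0.02)  # encoder noise, well below detection scales
  x <- rnorm(n, sd = 0.05)

  reward <- numeric(n)
  for (rt in trials$reward_time_s[!trials$omission]) {
    idx <- which(tt >= rt & tt < rt + 0.05)
    reward[idx] <- 1
  }

  lick <- simulate_lick_stream(tt, trials, config)

  out <- list(trials = trials,
              behavior = data.frame(t = tt, x = x, y = y,
                                    reward = reward, lick = lick),
              duration_s = duration)
  class(out) <- "synth_trials"
  out
}

# Inhomogeneous-Poisson lick-sensor contacts from an expertise-dependent
# rate template; 35 ms contact duration, 60 ms refractory between onsets.
simulate_lick_stream <- function(tt, trials, config) {
  set.seed(derive_seed(config$seed, "lick"))
  dt <- tt[2] - tt[1]
  delay <- config$delay_s
  rate <- rep(0.2, length(tt))
  expert <- config$expertise == "expert"
  for (j in seq_len(nrow(trials))) {
    rw <- trials$reward_time_s[j]
    # delay-period template
    idx <- which(tt >= rw - delay & tt < rw)
    frac <- (tt[idx] - (rw - delay)) / delay
    rate[idx] <- if (expert) 0.3 + 3.5 * frac else 0.3 + 2.5 * (1 - frac)
    # post-reward template
    idx <- which(tt >= rw & tt < rw + 2.5)
    tau <- tt[idx] - rw
    rate[idx] <- if (!trials$omission[j]) {
      if (expert) 6 * exp(-tau / 0.8) else 5 * exp(-tau / 0.5)
    } else {
      if (expert) 2 * exp(-tau / 0.25) else 1 * exp(-tau / 0.25)
    }
  }
  p <- pmin(1, rate * dt)
  events <- which(runif(length(tt)) < p)
  lick <- numeric(length(tt))
  contact <- max(1L, round(0.035 / dt))
  refract <- 0.06
  last <- -Inf
  for (e in events) {
    if (tt[e] - last < refract) next
    last <- tt[e]
    lick[e:min(length(tt), e + contact - 1L)] <- 1
  }
  lick
}
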