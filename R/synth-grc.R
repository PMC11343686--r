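#' Simulate a granule-cell population with ground truth
#'
#' Builds per-cell activity profiles on the trial scaffold, convolves them
#' with a single-exponential calcium kernel, and adds measurement noise; a
#' raw-fluorescence version additionally carries slow additive drift and a
#' multiplicative double-exponential bleaching envelope.
#'
#' Cell classes (`anticipatory`, `movement_transient`, `reward_transient`,
#' `silent`) are drawn in configured proportions. Expert anticipatory cells
#' are long overlapping piecewise-linear ramps on a movement-midpoint
#' timebase: peak phase tiles the learned span uniformly and rise/fall
#' half-widths are comparable to the span, so each cell's activity at reward
#' is a graded, nonzero snapshot of its peak phase while within-delay
#' activity mass is roughly phase-independent. Profiles are truncated
#' ~0.2 s after reward on rewarded trials and prolonged by a per-cell
#' `omission_prolongation_s` on omission trials. Novice anticipatory cells
#' carry brief early-delay transients instead. All cells additionally emit
#' sparse spontaneous (task-unrelated) transients, and every (cell, trial)
#' response is scaled by a lognormal gain.
#'
#' @param config a [synth_config()].
#' @param trials a [simulate_trials()] result.
#' @return A list of class `synth_grc`:
#' \describe{
#'   \item{z}{cells x frames matrix: noiseless signal plus unit-calibrated
#'     noise (z-score scale), no bleach or drift.}
#'   \item{raw}{cells x frames matrix of synthetic raw fluorescence
#'     (positive, bleached, drifting).}
#'   \item{signal}{cells x frames noiseless kernel-convolved signal.}
#'   \item{frame_times_s}{frame clock, seconds.}
#'   \item{truth}{per-cell data.frame: `cell`, `class`, `onset_s`,
#'     `peak_time_s` (both relative to the movement midpoint), `rise_rate`,
#'     `amp`, `end_frac` (terminal activity fraction at reward),
#'     `dec_end_s` (fall half-width), `center_time_s` (rectified activity
#'     centroid of the kernel-convolved canonical profile, relative to
#'     reward, in [-delay, 0]), `omission_prolongation_s`.}
#' }
#' @examples
#' cfg <- synth_config(n_grc = 12, n_cf = 3, n_trials = 6, seed = 2)
#' g <- simulate_grc_population(cfg, simulate_trials(cfg))
#' table(g$truth$class)
#' @export
simulate_grc_population <- function(config, trials) {
  stopifnot(inherits(config, "synth_config"), inherits(trials, "synth_trials"))
  if (config$frac_anticipatory < 0 || config$frac_anticipatory > 1)
    stop("'frac_anticipatory' must be in [0, 1]")
  set.seed(derive_seed(config$seed, "grc"))
  fs <- config$frame_rate_hz
  dtf <- 1 / fs
  ft <- seq(0, trials$duration_s, by = dtf)
  nf <- length(ft)
  n <- config$n_grc
  delay <- config$delay_s
  dbasis <- min(config$basis_delay_s, delay)
  tb <- trials$trials

  n_ant <- round(config$frac_anticipatory * n)
  n_mov <- round(config$frac_grc_movement * n)
  n_rew <- round(config$frac_grc_reward * n)
  if (n_ant + n_mov + n_rew > n) stop("GrC class fractions exceed 1")
  classes <- sample(c(rep("anticipatory", n_ant), rep("movement_transient", n_mov),
                      rep("reward_transient", n_rew),
                      rep("silent", n - n_ant - n_mov - n_rew)))

  novice <- config$expertise == "novice"
  truth <- data.frame(cell = seq_len(n), class = classes,
                      onset_s = NA_real_, peak_time_s = NA_real_,
                      rise_rate = NA_real_, amp = NA_real_,
                      end_frac = NA_real_, dec_end_s = NA_real_,
                      hold_frac = NA_real_, center_time_s = NA_real_,
                      omission_prolongation_s = NA_real_,
                      stringsAsFactors = FALSE)

  signal <- matrix(0, n, nf)
  for (ci in seq_len(n)) {
    cls <- classes[ci]
    if (cls == "silent") next
    amp <- runif(1, 2, 5)  # transient amplitude, z-scores (bright somata)
    if (cls == "anticipatory") {
      # Expert profiles are long overlapping ramps of differing kinetics on
      # a movement-midpoint timebase: the peak time tiles the learned span
      # S = basis_delay + 0.2, and rise/fall half-widths are comparable to
      # the span, so (i) activity at reward is a graded snapshot of each
      # cell's peak phase (the fall limb has not returned to zero), and
      # (ii) within-delay activity mass is roughly peak-phase-independent.
      # Novice profiles are brief early transients instead.
      S <- dbasis + 0.2          # movement midpoint to (learned) reward
      Sf <- S / 1.3              # kinetic scale factor vs the 1.1-s task
      if (novice) {
        # day-1-like anticipation: brief early transients, weaker amplitude
        # and looser trial locking than after learning
        p_b <- runif(1, -(S - 0.08), -(S - 0.08) + 0.3 * S)
        h_r <- runif(1, 0.08, 0.2)
        h_f <- runif(1, 0.15, 0.35)
        e <- max(0.01, 1 + p_b / h_f)
        amp <- amp * 0.6
      } else {
        p_b <- runif(1, -(S - 0.05), -0.05)  # peak time rel learned reward
        h_r <- runif(1, 1.3, 2.0) * Sf       # rise half-width
        # fall half-width: lower bound keeps fall rates bounded (~1.4/s),
        # so late-peaked cells do not crash just before reward
        h_f <- runif(1, max(-p_b + 0.15, 0.7 * Sf), -p_b + 1.6 * Sf)
        e <- 1 + p_b / h_f                   # terminal fraction at reward
        hold_frac <- 1
      }
      peak_rel <- S + p_b                    # peak time rel movement
      onset_rel <- max(0, peak_rel - h_r)
      v0 <- max(0, 1 - (peak_rel - onset_rel) / h_r)
      prolong <- runif(1, 0.2, 0.6)
      truth$onset_s[ci] <- onset_rel; truth$peak_time_s[ci] <- peak_rel
      truth$rise_rate[ci] <- amp / h_r
      truth$amp[ci] <- amp; truth$end_frac[ci] <- e
      truth$dec_end_s[ci] <- h_f
      truth$hold_frac[ci] <- if (novice) NA_real_ else hold_frac
      truth$omission_prolongation_s[ci] <- prolong
      for (j in seq_len(nrow(tb))) {
        gain <- rlnorm(1, 0, 0.25)
        mid_t <- tb$reach_mid_s[j] + rnorm(1, 0, if (novice) 0.12 else 0.05)
        rr <- tb$reward_time_s[j]
        off <- rr + 0.2 +
          (if (tb$omission[j]) prolong else 0) + rnorm(1, 0, 0.05)
        vr <- min(mid_t + S, rr - 1e-6)      # learned-span end (saturation)
        peak_t <- mid_t + peak_rel
        hold_t <- if (novice) peak_t + h_f else vr
        hold_t <- min(hold_t, vr - 1e-6)
        bp <- c(mid_t + onset_rel, peak_t, hold_t, vr, rr, off, off + 0.12)
        vals <- gain * amp * c(v0, 1, e, e, e, e, 0)
        ok <- c(TRUE, diff(bp) > 1e-9)
        bp <- bp[ok]; vals <- vals[ok]
        idx <- which(ft >= bp[1] & ft <= bp[length(bp)])
        if (length(idx) < 2L || length(bp) < 2L) next
        prof <- approx(bp, vals, xout = ft[idx], yleft = 0, yright = 0)$y
        signal[ci, idx] <- signal[ci, idx] + prof
      }
    } else if (cls == "movement_transient") {
      w <- runif(1, 0.15, 0.25)
      truth$amp[ci] <- amp
      for (j in seq_len(nrow(tb))) {
        gain <- rlnorm(1, 0, 0.25)
        ctr <- tb$reach_mid_s[j] + rnorm(1, 0, 0.04)
        bp <- c(ctr - w, ctr, ctr + w)
        idx <- which(ft >= bp[1] & ft <= bp[3])
        if (length(idx) < 2L) next
        prof <- approx(bp, gain * amp * c(0, 1, 0), xout = ft[idx],
                       yleft = 0, yright = 0)$y
        signal[ci, idx] <- signal[ci, idx] + prof
      }
    } else if (cls == "reward_transient") {
      w <- runif(1, 0.15, 0.25)
      truth$amp[ci] <- amp
      for (j in which(!tb$omission)) {
        gain <- rlnorm(1, 0, 0.25)
        ctr <- tb$reward_time_s[j] + 0.15 + rnorm(1, 0, 0.08)
        bp <- c(ctr - w, ctr, ctr + w)
        idx <- which(ft >= bp[1] & ft <= bp[3])
        if (length(idx) < 2L) next
        prof <- approx(bp, gain * amp * c(0, 1, 0), xout = ft[idx],
                       yleft = 0, yright = 0)$y
        signal[ci, idx] <- signal[ci, idx] + prof
      }
    }
  }

  # spontaneous (task-unrelated) transients: GrCs burst sparsely throughout
  # the session (inter-trial licks, postural adjustments, spontaneous
  # activity), at a per-cell rate independent of task tuning; this keeps a
  # cell's overall activity level uninformative about its task timing
  for (ci in seq_len(n)) {
    rate <- runif(1, 0.1, 0.8)
    amp_s <- if (is.finite(truth$amp[ci])) truth$amp[ci] else runif(1, 2, 5)
    n_ev <- rpois(1, rate * trials$duration_s)
    if (n_ev == 0) next
    ctrs <- runif(n_ev, 0, trials$duration_s)
    for (ctr in ctrs) {
      idx <- which(ft >= ctr - 0.15 & ft <= ctr + 0.15)
      if (length(idx) < 2L) next
      prof <- approx(c(ctr - 0.15, ctr, ctr + 0.15),
                     amp_s * rlnorm(1, 0, 0.25) * c(0, 1, 0),
                     xout = ft[idx], yleft = 0, yright = 0)$y
      signal[ci, idx] <- signal[ci, idx] + prof
    }
  }

  # indicator kinetics
  for (ci in seq_len(n)) {
    signal[ci, ] <- calcium_convolve(signal[ci, ], dtf, config$ca_tau_s)
  }

  # ground-truth anticipatory center times from the canonical (jitter-free,
  # rewarded-trial) kernel-convolved profile, rectified centroid in [-delay, 0]
  tau_grid <- seq(-delay - 1.5, 0.5, by = dtf)
  rr_nom <- delay + 0.2  # nominal midpoint-to-reward interval
  S_nom <- min(config$basis_delay_s, delay) + 0.2
  for (ci in which(classes == "anticipatory")) {
    onset_rel <- truth$onset_s[ci]; peak_rel <- truth$peak_time_s[ci]
    e <- truth$end_frac[ci]; amp <- truth$amp[ci]
    h_f <- truth$dec_end_s[ci]
    h_r <- amp / truth$rise_rate[ci]
    v0 <- max(0, 1 - (peak_rel - onset_rel) / h_r)
    vr <- min(S_nom, rr_nom - 1e-6)
    hold_t <- if (is.finite(truth$hold_frac[ci]))
      peak_rel + truth$hold_frac[ci] * (vr - peak_rel) else peak_rel + h_f
    hold_t <- min(hold_t, vr - 1e-6)
    bp <- c(onset_rel, peak_rel, hold_t, vr, rr_nom, rr_nom + 0.2,
            rr_nom + 0.32) - rr_nom
    vals <- amp * c(v0, 1, e, e, e, e, 0)
    ok <- c(TRUE, diff(bp) > 1e-9)
    prof <- approx(bp[ok], vals[ok], xout = tau_grid, yleft = 0, yright = 0)$y
    prof <- calcium_convolve(prof, dtf, config$ca_tau_s)
    idx <- which(tau_grid >= -delay & tau_grid <= 0)
    w <- pmax(prof[idx], 0)
    truth$center_time_s[ci] <- if (sum(w) > 0) sum(tau_grid[idx] * w) / sum(w) else NA_real_
  }

  set.seed(derive_seed(config$seed, "noise"))
  noise <- matrix(0, n, nf)
  drift <- matrix(0, n, nf)
  for (ci in seq_len(n)) {
    noise[ci, ] <- config$noise_sigma *
      fluor_noise(nf, dtf, config$ca_tau_s, config$noise_white_frac)
    per <- runif(2, 180, 600); ph <- runif(2, 0, 2 * pi)
    drift[ci, ] <- config$drift_amp * config$noise_sigma *
      (sin(2 * pi * ft / per[1] + ph[1]) + sin(2 * pi * ft / per[2] + ph[2])) / 2
  }
  z <- signal + noise

  bp <- config$bleach_params
  bleach <- bp$amps[1] * exp(-ft / bp$taus[1]) + bp$amps[2] * exp(-ft / bp$taus[2])
  raw <- sweep(bp$f0 + bp$gain * (signal + noise + drift), 2, bleach, `*`)

  out <- list(z = z, raw = raw, signal = signal, frame_times_s = ft,
              truth = truth)
  class(out) <- "synth_grc"
  out
}
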