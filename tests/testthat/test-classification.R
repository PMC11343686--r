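# Trial alignment and window-based response classification.

test_that("a delta at reward aligns to the t = 0 column", {
  fs <- 30
  tt_abs <- seq(0, 60, by = 1 / fs)
  # reward times snapped to the frame grid to make the mapping exact
  rewards <- tt_abs[c(301, 901, 1501)]
  traces <- matrix(0, 2, length(tt_abs))
  traces[, c(301, 901, 1501)] <- 1
  tb <- data.frame(trial = 1:3, reach_mid_s = rewards - 1.3,
                   reward_time_s = rewards, omission = FALSE)
  tens <- align_to_trials(traces, tt_abs, tb, "reward", c(-0.5, 0.5))
  tta <- tensor_time(tens)
  zero_col <- which.min(abs(tta))
  expect_true(all(tens[, zero_col, ] == 1))
  expect_true(all(tens[, -zero_col, ] == 0))
})

test_that("concatenated alignment places the movement midpoint at -delay", {
  fs <- 30
  tt_abs <- seq(0, 60, by = 1 / fs)
  mids <- tt_abs[c(200, 800, 1400)]
  rewards <- mids + 1.1
  traces <- matrix(0, 1, length(tt_abs))
  traces[, c(200, 800, 1400)] <- 1
  tb <- data.frame(trial = 1:3, reach_mid_s = mids, reward_time_s = rewards,
                   omission = FALSE)
  tens <- align_to_trials(traces, tt_abs, tb, "concatenated", c(-1.4, 0.3),
                          delay_s = 1.1)
  tta <- tensor_time(tens)
  mid_col <- which.min(abs(tta + 1.1))
  expect_true(all(tens[, mid_col, ] == 1))
})

test_that("alignment round-trips generator profiles", {
  ses <- fixture_session()
  tens <- reward_tensor(ses, traces = ses$grc$signal)
  tta <- tensor_time(tens)
  avg <- tensor_trial_average(tens)
  tr <- ses$grc$truth
  # reward-transient cells peak just after reward; anticipatory cells carry
  # most rectified mass inside the delay
  for (ci in which(tr$class == "reward_transient")) {
    pk <- tta[which.max(avg[ci, ])]
    expect_gt(pk, 0)
    expect_lt(pk, 0.6)
  }
  for (ci in which(tr$class == "movement_transient")) {
    pk <- tta[which.max(avg[ci, ])]
    expect_lt(pk, -ses$config$delay_s + 0.35)
  }
})

test_that("windows beyond the session bounds drop trials with a message", {
  ses <- fixture_session()
  expect_message(
    tens <- align_to_trials(ses$grc$z, ses$frame_times_s, ses$trials,
                            "reward", c(-8, 0.5)),
    "dropped")
  expect_lt(dim(tens)[3], nrow(ses$trials))
})

test_that("classify_modulated applies both the p-value and magnitude rules", {
  set.seed(31)
  fs <- 30
  tta <- seq(-1, 1, by = 1 / fs)
  n_tr <- 50
  base <- array(rnorm(3 * length(tta) * n_tr, sd = 0.3),
                dim = c(3, length(tta), n_tr))
  # cell 1: +0.5 z in the test window; cell 2: +0.1 z (sub-magnitude);
  # cell 3: unmodulated
  wi <- tta >= 0 & tta <= 0.5
  base[1, wi, ] <- base[1, wi, ] + 0.5
  base[2, wi, ] <- base[2, wi, ] + 0.1
  tens <- make_tensor(base, tta)
  res <- classify_modulated(tens, c(0, 0.5), c(-1, -0.5))
  expect_true(res$modulated[1])
  expect_false(res$modulated[2])  # magnitude rule blocks it regardless of p
  expect_lt(res$p[2], 0.05)      # p alone would have flagged it
  expect_false(res$modulated[3])
  # identical windows are never flagged
  same <- classify_modulated(tens, c(0, 0.5), c(0, 0.5))
  expect_false(any(same$modulated))
  expect_error(classify_modulated(make_tensor(base[, , 1, drop = FALSE], tta),
                                  c(0, 0.5), c(-1, -0.5)), "2 trials")
})

test_that("anticipatory classifier accepts ramps and rejects reward bursts", {
  fs <- 30
  tta <- seq(-1.5, 0.6, by = 1 / fs)
  n_tr <- 20
  ramp <- pmax(0, pmin(1, (tta + 1) / 0.9)) * (tta <= 0) +
    pmax(0, 1 - (tta) / 0.2) * (tta > 0) * (tta <= 0.2)
  burst <- ifelse(tta > 0.05 & tta < 0.45, 1, 0)
  arr <- array(0, dim = c(2, length(tta), n_tr))
  for (k in seq_len(n_tr)) {
    arr[1, , k] <- ramp + rnorm(length(tta), sd = 0.3)
    arr[2, , k] <- burst + rnorm(length(tta), sd = 0.3)
  }
  res <- classify_anticipatory_grcs(make_tensor(arr, tta))
  expect_true(res$anticipatory[1])
  expect_false(res$anticipatory[2])
  expect_error(classify_anticipatory_grcs(
    make_tensor(arr[, tta > -1, , drop = FALSE], tta[tta > -1])), "span")
})

test_that("classifier fractions recover generator truth on a 100-trial session", {
  ses <- fixture_session("class100", n_grc = 80, n_cf = 16, n_trials = 100,
                         seed = 77)
  tens <- reward_tensor(ses)
  res <- classify_anticipatory_grcs(tens)
  # ground truth for the classifier's own rule, from noiseless signals
  sig <- reward_tensor(ses, traces = ses$grc$signal)
  truth <- classify_anticipatory_grcs(sig)
  strong <- truth$late_delay - truth$pre > 0.5 &
    truth$late_delay - truth$post > 0.5
  clean_neg <- truth$late_delay - truth$pre < 0.05 |
    truth$late_delay - truth$post < 0.05
  expect_gte(mean(res$anticipatory[strong]), 0.9)             # sensitivity
  expect_gte(mean(!res$anticipatory[clean_neg]), 0.9)         # specificity
  # recovered fraction within binomial error of the noiseless-rule fraction
  expect_lt(abs(mean(res$anticipatory) - mean(truth$anticipatory)),
            3 * sqrt(0.3 * 0.7 / nrow(res)) + 0.05)
})

test_that("reward-CF classifier recovers the responsive set", {
  # wide CF pool so sensitivity/specificity estimates are stable
  ses <- fixture_session("cfclass", n_grc = 10, n_cf = 40, n_trials = 100,
                         seed = 78)
  rates <- true_cf_rates(ses)
  tens <- reward_tensor(ses, traces = standardize_rates(rates))
  res <- classify_reward_cfs(tens)
  tr <- ses$cf$truth
  expect_gte(mean(res$reward_cf[tr$reward_responsive]), 0.9)
  # clean negatives: neither reward-responsive nor delay-suppressed (the
  # latter rebound at reward and genuinely satisfy the relative rule).
  # The 0.1-zsc dual criterion carries an intrinsic ~10% false-positive
  # rate against a 1 Hz Poisson background at 100 trials, so specificity
  # is asserted at 0.85.
  clean_neg <- !tr$reward_responsive & !tr$suppressed_during_delay
  expect_gte(mean(!res$reward_cf[clean_neg]), 0.85)
})

test_that("labels are invariant to trial-order permutation", {
  ses <- fixture_session()
  tens <- reward_tensor(ses)
  perm <- sample(dim(tens)[3])
  tens_p <- make_tensor(unclass(tens)[, , perm],
                        tensor_time(tens),
                        trial_ids = attr(tens, "trial_ids")[perm])
  expect_equal(classify_anticipatory_grcs(tens)$anticipatory,
               classify_anticipatory_grcs(tens_p)$anticipatory)
})

test_that("anticipation off-time finds the 50% crossing", {
  fs <- 30
  tta <- seq(-1, 1.5, by = 1 / fs)
  # step down at +0.3 s
  tr <- ifelse(tta < 0.3, 1, 0.1)
  off <- anticipation_offtime(tta, tr)
  expect_true(off$defined)
  expect_equal(off$off_time_s, 0.3, tolerance = 0.04)
  expect_false(anticipation_offtime(tta, rep(0, length(tta)))$defined)
})

test_that("omission prolongs anticipation off-times and CF onset times", {
  ses <- fixture_session("class100", n_grc = 80, n_cf = 16, n_trials = 100,
                         seed = 77)
  ant <- which(ses$grc$truth$class == "anticipatory" &
                 ses$grc$truth$end_frac > 0.4)
  off_med <- function(subset) {
    tens <- reward_tensor(ses, subset = subset, post = 1.2)
    tta <- tensor_time(tens)
    avg <- tensor_trial_average(tens)
    median(vapply(ant, function(ci)
      anticipation_offtime(tta, avg[ci, ])$off_time_s, numeric(1)),
      na.rm = TRUE)
  }
  expect_gt(off_med("omission"), off_med("rewarded"))
  # CF population spiking also rises later on omission trials
  rates <- true_cf_rates(ses)
  rr <- which(ses$cf$truth$reward_responsive)
  # absolute threshold from the rewarded trials' reward response
  rew_tens <- reward_tensor(ses, traces = rates, subset = "rewarded",
                            post = 1.2)
  rew_avg <- colMeans(tensor_trial_average(rew_tens)[rr, ])
  rt <- tensor_time(rew_tens)
  thr <- quantile(rew_avg[rt >= 0 & rt <= 0.2], 0.2, names = FALSE)
  onset_med <- function(subset) {
    tens <- reward_tensor(ses, traces = rates, subset = subset, post = 1.2)
    tta <- tensor_time(tens)
    vals <- vapply(seq_len(dim(tens)[3]), function(k)
      cf_onset_time(tta, colMeans(matrix(tens[rr, , k], length(rr))),
                    threshold = thr)$onset_s, numeric(1))
    median(vals, na.rm = TRUE)
  }
  expect_gt(onset_med("omission"), onset_med("rewarded"))
})

test_that("center times behave at symmetric cases and recover ground truth", {
  fs <- 30
  tta <- seq(-1.5, 0.5, by = 1 / fs)
  bump <- exp(-(tta + 0.5)^2 / (2 * 0.1^2))
  expect_equal(anticipatory_center_time(tta, bump, c(-1.1, 0)), -0.5,
               tolerance = 0.02)
  expect_equal(anticipatory_center_time(tta, rep(1, length(tta)), c(-1, 0)),
               -0.5, tolerance = 0.02)
  expect_true(is.na(anticipatory_center_time(tta, rep(-1, length(tta)),
                                             c(-1, 0))))
  # elevated-timepoint variant agrees for the symmetric bump
  expect_equal(anticipatory_center_time(tta, bump, c(-1.1, 0),
                                        method = "elevated_center"), -0.5,
               tolerance = 0.05)
  # recovery on a 100-trial session at noise sigma = 1
  ses <- fixture_session("class100", n_grc = 80, n_cf = 16, n_trials = 100,
                         seed = 77)
  tens <- reward_tensor(ses)
  tta2 <- tensor_time(tens)
  avg <- tensor_trial_average(tens)
  tr <- ses$grc$truth
  ant <- which(tr$class == "anticipatory")
  est <- vapply(ant, function(ci)
    anticipatory_center_time(tta2, avg[ci, ], c(-1.1, 0)), numeric(1))
  err <- abs(est - tr$center_time_s[ant])
  expect_lt(median(err, na.rm = TRUE), 0.1)
  expect_lt(quantile(err, 0.9, na.rm = TRUE), 0.2)
})

test_that("elevated duration measures time above baseline", {
  fs <- 30
  tta <- seq(-1.2, 2.5, by = 1 / fs)
  trap <- ifelse(tta > 0.4 & tta <= 1.4, 1, 0)
  expect_equal(elevated_duration(tta, trap), 1, tolerance = 0.05)
  expect_equal(elevated_duration(tta, rep(0, length(tta))), 0)
  # longer-delay experts sustain activity longer than 1-s experts
  dur_of <- function(delay, key) {
    ses <- fixture_session(key, n_grc = 60, n_cf = 8, n_trials = 40,
                           delay_s = delay, seed = 55)
    tens <- align_to_trials(ses$grc$z, ses$frame_times_s, ses$trials,
                            "movement", c(-1.1, 2.5), subset = "rewarded")
    tta3 <- tensor_time(tens)
    avg <- tensor_trial_average(tens)
    ant <- which(ses$grc$truth$class == "anticipatory")
    median(vapply(ant, function(ci)
      elevated_duration(tta3, avg[ci, ]), numeric(1)))
  }
  expect_gt(dur_of(2, "exp2s"), dur_of(1, "exp1s"))
})
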