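#' Weighted-sum GrC readout (predicted PkC component)
#'
#' Computes, per trial and frame, the weighted sum of GrC activity using a
#' weight set's readout vector (or any numeric weight vector), the pooled
#' correlation between frame time and readout over a window, and an
#' affinely normalized trial-average whose range is mapped onto the
#' window's time span (the display/accuracy convention for these readouts).
#'
#' @param grc_tensor `aligned_tensor`, cells x time x trials.
#' @param weights a `weight_set` or numeric vector of length n_grc.
#' @param window evaluation window on the tensor's time axis; defaults to
#'   the full axis.
#' @return A list of class `readout_result`: `per_trial` (time x trials
#'   matrix), `trial_avg`, `trial_avg_scaled` (trial-average affinely mapped
#'   onto the window time range, orientation chosen by the sign of the
#'   time-readout correlation), `time_s`, `r` (pooled time-readout
#'   correlation; NA with `r_defined = FALSE` for flat readouts),
#'   `r_per_trial`, `provenance`.
#' @export
weighted_readout <- function(grc_tensor, weights, window = NULL) {
  prov <- "custom"
  if (inherits(weights, "weight_set")) {
    prov <- weights$provenance
    weights <- weights$readout_vector
  }
  if (length(weights) != dim(grc_tensor)[1])
    stop("weight length (", length(weights), ") != n_grc (",
         dim(grc_tensor)[1], ")")
  tt <- tensor_time(grc_tensor)
  if (is.null(window)) window <- range(tt)
  idx <- window_idx(tt, window)
  n_trials <- dim(grc_tensor)[3]
  n_grc <- dim(grc_tensor)[1]
  per_trial <- vapply(seq_len(n_trials), function(k)
    as.numeric(weights %*% matrix(grc_tensor[, idx, k], n_grc)),
    numeric(length(idx)))
  per_trial <- matrix(per_trial, length(idx), n_trials)
  trial_avg <- rowMeans(per_trial)
  tt_w <- tt[idx]

  pooled_t <- rep(tt_w, n_trials)
  pooled_y <- as.vector(per_trial)
  r_defined <- sd(pooled_y) > 0
  r <- if (r_defined) cor(pooled_t, pooled_y) else NA_real_
  r_per_trial <- apply(per_trial, 2, function(v)
    if (sd(v) > 0) cor(tt_w, v) else NA_real_)

  rng <- range(trial_avg)
  scaled <- if (diff(rng) > 0) {
    s <- (trial_avg - rng[1]) / diff(rng)
    if (is.finite(r) && r < 0) s <- 1 - s
    window[1] + s * diff(window)
  } else rep(mean(window), length(trial_avg))

  structure(list(per_trial = per_trial, trial_avg = trial_avg,
                 trial_avg_scaled = scaled, time_s = tt_w, r = r,
                 r_defined = r_defined, r_per_trial = r_per_trial,
                 weights = weights, window = window, provenance = prov),
            class = "readout_result")
}

#' @export
print.readout_result <- function(x, ...) {
  cat("<readout_result> provenance=", x$provenance, ", ",
      length(x$time_s), " frames x ", ncol(x$per_trial), " trials, pooled r=",
      signif(x$r, 3), "\n", sep = "")
  invisible(x)
}

#' Timing accuracy (R^2) of a readout over a window
#'
#' Pooled coefficient of determination between frame time and the
#' single-trial readout values over the window: the R^2 of the
#' least-squares linear map from readout to time, pooled across trials
#' (equal to the squared pooled time-readout correlation). A readout that
#' saturates or decays partway through the window scores strictly lower
#' than one that tracks time throughout.
#'
#' @param readout a `readout_result` (or an `aligned_tensor`, in which case
#'   `weights` must be given and the readout is computed first).
#' @param window evaluation window; defaults to the readout's window.
#' @param weights weights when `readout` is a tensor.
#' @return List with `r2`, `r` (pooled correlation), `n` (pooled samples).
#' @export
timing_accuracy <- function(readout, window = NULL, weights = NULL) {
  if (inherits(readout, "aligned_tensor")) {
    readout <- weighted_readout(readout, weights, window)
  }
  stopifnot(inherits(readout, "readout_result"))
  if (is.null(window)) window <- readout$window
  idx <- window_idx(readout$time_s, window)
  tt <- readout$time_s[idx]
  pooled_t <- rep(tt, ncol(readout$per_trial))
  pooled_y <- as.vector(readout$per_trial[idx, ])
  if (sd(pooled_y) == 0) return(list(r2 = NA_real_, r = NA_real_, n = 0L))
  r <- cor(pooled_t, pooled_y)
  list(r2 = r^2, r = r, n = length(pooled_t))
}

#' Cross-validated linear decoding of elapsed time
#'
#' 10-fold cross-validated ordinary least squares: trials are concatenated
#' along the time axis into a (trials x frames)-by-cells design matrix, the
#' target is the relative time axis repeated per trial, folds partition
#' *trials* (never frames, avoiding within-trial temporal leakage), and
#' held-out predictions are pooled into R^2 and mean absolute error.
#'
#' @param grc_tensor `aligned_tensor` restricted (via `window`) to the
#'   decoded epoch, e.g. the delay `[-1.1, 0]` s.
#' @param window decoding window on the tensor time axis; default full axis.
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @return A list of class `decoding_result`: `predictions` (time x trials
#'   matrix of held-out predictions), `r2`, `mae_ms`, `fold` (per-trial fold
#'   index), `time_s`.
#' @export
decode_time_cv <- function(grc_tensor, window = NULL, folds = 10, seed = 1L) {
  tt <- tensor_time(grc_tensor)
  if (is.null(window)) window <- range(tt)
  idx <- window_idx(tt, window)
  tt_w <- tt[idx]
  n_trials <- dim(grc_tensor)[3]
  n_grc <- dim(grc_tensor)[1]
  if (n_trials < folds) stop("need at least as many trials as folds")
  n_train_min <- (n_trials - ceiling(n_trials / folds)) * length(tt_w)
  if (n_grc + 1L >= n_train_min)
    stop("ill-posed OLS: n_grc + intercept >= training samples; ",
         "reduce cells or use a ridge-regularized decoder")
  set.seed(derive_seed(seed, "folds"))
  fold <- sample(rep_len(seq_len(folds), n_trials))
  pred <- matrix(NA_real_, length(tt_w), n_trials)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te)) next
    Xtr <- t(matrix(grc_tensor[, idx, tr], n_grc))
    ytr <- rep(tt_w, times = length(tr))
    fit <- lm.fit(cbind(1, Xtr), ytr)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    Xte <- t(matrix(grc_tensor[, idx, te], n_grc))
    pred[, te] <- matrix(cbind(1, Xte) %*% beta, length(tt_w))
  }
  y <- rep(tt_w, times = n_trials)
  yhat <- as.vector(pred)
  r2 <- 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)
  structure(list(predictions = pred, r2 = r2,
                 mae_ms = mean(abs(yhat - y)) * 1000, fold = fold,
                 time_s = tt_w, window = window, folds = folds, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", x$folds, "-fold CV over [", x$window[1], ", ",
      x$window[2], "] s: R^2=", signif(x$r2, 3), ", MAE=",
      signif(x$mae_ms, 4), " ms\n", sep = "")
  invisible(x)
}

#' Compare readout provenances and the optimal decoder on one session
#'
#' Evaluates |r| and timing R^2 for each supplied weight set on the same
#' tensor/window, and appends the cross-validated OLS decoder as the
#' optimal-readout reference.
#'
#' @param grc_tensor `aligned_tensor`.
#' @param weight_sets named list of `weight_set` objects.
#' @param window evaluation window.
#' @param decoder_seed fold seed for the reference decoder; set `NULL` to
#'   skip it.
#' @return data.frame: `provenance`, `abs_r`, `r2`.
#' @export
compare_readouts <- function(grc_tensor, weight_sets, window = NULL,
                             decoder_seed = 1L) {
  rows <- lapply(weight_sets, function(ws) {
    ro <- weighted_readout(grc_tensor, ws, window)
    acc <- timing_accuracy(ro)
    data.frame(provenance = ws$provenance, abs_r = abs(ro$r), r2 = acc$r2)
  })
  out <- do.call(rbind, rows)
  if (!is.null(decoder_seed)) {
    dec <- decode_time_cv(grc_tensor, window, seed = decoder_seed)
    out <- rbind(out, data.frame(provenance = "optimal_decoder",
                                 abs_r = NA_real_, r2 = dec$r2))
  }
  rownames(out) <- NULL
  out
}

#' Rank correlation between behavioral and readout timing across sessions
#'
#' Spearman correlation between per-session lick preference (behavioral
#' timing specificity) and per-session readout timing accuracy.
#'
#' @param lick_preference numeric vector, one value per session.
#' @param readout_accuracy numeric vector, same length.
#' @return List with `rho`, `p`, `n`.
#' @export
behavior_readout_correlation <- function(lick_preference, readout_accuracy) {
  stopifnot(length(lick_preference) == length(readout_accuracy))
  ok <- is.finite(lick_preference) & is.finite(readout_accuracy)
  ct <- suppressWarnings(cor.test(lick_preference[ok], readout_accuracy[ok],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
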