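#' Default pipeline configuration
#'
#' @return Nested list of defaults: `seed`, `output_dir`, `session_dir`
#'   (set to load a written session instead of simulating), `write_traces`
#'   (persist full trace matrices; off by default, tables and metrics are
#'   always persisted), `synth` ([synth_config()] fields), `conditioning`
#'   (`grc` and `cf` [conditioning_params()] overrides), `plasticity`
#'   ([plasticity_params()] fields) and `analysis` (alignment/decoding
#'   windows and fold count).
#' @export
default_run_config <- function() {
  list(seed = 1L, output_dir = NULL, session_dir = NULL, write_traces = FALSE,
       synth = list(), conditioning = list(grc = list(), cf = list()),
       plasticity = list(),
       analysis = list(pre_window_s = 0.6, post_window_s = 0.6,
                       post_reward_window_s = c(1, 2), decode_folds = 10L,
                       use_generator_z = FALSE))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills defaults from
#' [default_run_config()], and rejects unknown keys and malformed windows.
#' An empty file yields the all-defaults config; validation is idempotent.
#'
#' @param config YAML path, nested list, or `run_config`.
#' @return A `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  config <- unclass(config)
  # NULL entries mean "use the default"; dropping them keeps modifyList from
  # deleting keys (and makes validation idempotent)
  config <- config[!vapply(config, is.null, logical(1))]
  defaults <- default_run_config()
  check_keys <- function(x, ref, path) {
    bad <- setdiff(names(x), names(ref))
    if (length(bad)) stop("unknown config key(s) at ", path, ": ",
                          paste(bad, collapse = ", "))
  }
  check_keys(config, defaults, "top level")
  check_keys(config$synth %||% list(),
             formals(synth_config), "synth")
  check_keys(config$conditioning %||% list(), defaults$conditioning,
             "conditioning")
  for (k in c("grc", "cf"))
    check_keys(config$conditioning[[k]] %||% list(),
               formals(conditioning_params), paste0("conditioning$", k))
  check_keys(config$plasticity %||% list(), formals(plasticity_params),
             "plasticity")
  check_keys(config$analysis %||% list(), defaults$analysis, "analysis")
  out <- modifyList(defaults, config)
  prw <- out$analysis$post_reward_window_s
  if (length(prw) != 2L || prw[1] >= prw[2])
    stop("analysis$post_reward_window_s must be an increasing length-2 window")
  if (out$analysis$pre_window_s < 0 || out$analysis$post_window_s < 0)
    stop("analysis window extensions must be >= 0")
  out$seed <- as.integer(out$seed)
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on one (synthetic) session
#'
#' Executes generate (or load) -> condition -> behavior -> align ->
#' classify -> plasticity -> readout/decoding, persists tabular
#' intermediates under `output_dir`, and returns (and writes) a
#' machine-readable report aggregating classification fractions, the
#' LTD-weight-versus-center-time correlation, and readout/decoding
#' accuracies for every provenance. Identical configs produce identical
#' reports.
#'
#' @param config anything accepted by [validate_config()].
#' @param output_dir overrides `config$output_dir`; `NULL` disables
#'   persistence.
#' @return The report, a nested list (also written as `report.json`).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  odir <- cfg$output_dir
  if (!is.null(odir)) dir.create(odir, showWarnings = FALSE, recursive = TRUE)
  persist <- function(df, name) {
    if (!is.null(odir)) data.table::fwrite(df, file.path(odir, name))
  }
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  report <- list(seed = cfg$seed, stages = character(0))

  ses <- stage("simulate", {
    if (!is.null(cfg$session_dir)) read_session(cfg$session_dir)
    else {
      sc <- do.call(synth_config, modifyList(cfg$synth, list(seed = cfg$seed)))
      simulate_session(sc)
    }
  })
  delay <- ses$config$delay_s
  fs <- ses$config$frame_rate_hz
  report$session <- list(n_grc = nrow(ses$grc$z), n_cf = nrow(ses$cf$z),
                         n_trials = nrow(ses$trials), delay_s = delay,
                         expertise = ses$config$expertise)
  if (!is.null(odir) && cfg$write_traces) write_session(ses, file.path(odir, "session"))

  cond <- stage("condition", {
    if (isTRUE(cfg$analysis$use_generator_z)) {
      list(grc_z = ses$grc$z, cf_z = ses$cf$z)
    } else {
      gp <- do.call(conditioning_params,
                    modifyList(list(kind = "grc"), cfg$conditioning$grc))
      cp <- do.call(conditioning_params,
                    modifyList(list(kind = "cf"), cfg$conditioning$cf))
      list(grc_z = condition_traces(ses$grc$raw, fs, gp),
           cf_z = condition_traces(ses$cf$raw, fs, cp),
           cf_params = cp)
    }
  })
  cf_params <- cond$cf_params %||% conditioning_params("cf")
  spk <- stage("deconvolve", infer_cf_spikes(cond$cf_z, fs, cf_params,
                                             ses$frame_times_s))

  beh <- stage("behavior", {
    reaches <- detect_reaches(ses$behavior$y, ses$config$behav_rate_hz)
    pulses <- ses$behavior$t[diff(c(0, ses$behavior$reward)) == 1]
    tb <- build_trial_table(reaches, pulses, delay)
    lr <- lick_rate_trace(ses$behavior$lick, ses$config$behav_rate_hz)
    spans <- cbind(tb$reach_start_s, tb$reward_time_s + 2)
    valid <- lick_validity_mask(ses$behavior$lick, ses$config$behav_rate_hz,
                                spans)
    # reward-aligned lick rates on valid trials
    bt <- ses$behavior$t
    rel <- seq(-delay, 2, by = 1 / ses$config$behav_rate_hz)
    keep <- which(valid & !tb$omission)
    lick_mat <- t(vapply(keep, function(j) {
      idx <- pmin(length(bt), pmax(1L, round((tb$reward_time_s[j] + rel) *
                                               ses$config$behav_rate_hz) + 1L))
      lr[idx]
    }, numeric(length(rel))))
    pref <- lick_preference(rel, lick_mat)
    offs <- vapply(seq_len(nrow(lick_mat)), function(i)
      lick_offtime(rel, lick_mat[i, ])$off_time_s, numeric(1))
    list(trial_table = tb, valid = valid, preference = pref$preference,
         median_offtime_s = median(offs, na.rm = TRUE))
  })
  tb <- beh$trial_table
  persist(tb, "trials.csv")
  report$behavior <- list(n_trials_detected = nrow(tb),
                          n_valid_lick = sum(beh$valid),
                          lick_preference = beh$preference,
                          median_lick_offtime_s = beh$median_offtime_s)

  win <- c(-delay - cfg$analysis$pre_window_s, cfg$analysis$post_window_s)
  tens <- stage("align", {
    list(grc = align_to_trials(cond$grc_z, ses$frame_times_s, tb, "reward",
                               win, subset = "rewarded"),
         cf = align_to_trials(spk$rates, ses$frame_times_s, tb, "reward",
                              win, subset = "rewarded"),
         cf_z = align_to_trials(standardize_rates(spk$rates),
                                ses$frame_times_s, tb, "reward", win,
                                subset = "rewarded"))
  })

  labels <- stage("classify", {
    ant <- classify_anticipatory_grcs(tens$grc)
    rcf <- classify_reward_cfs(tens$cf_z)
    tta <- tensor_time(tens$grc)
    avg <- tensor_trial_average(tens$grc)
    centers <- vapply(seq_len(nrow(avg)), function(i)
      anticipatory_center_time(tta, avg[i, ], c(-delay, 0)), numeric(1))
    # a center of delay activity is only meaningful for cells whose
    # rectified delay-period average rises above the trial-average noise
    # floor (~1/sqrt(n_trials)); mask the rest
    di <- window_idx(tta, c(-delay, 0))
    mass <- vapply(seq_len(nrow(avg)), function(i)
      mean(pmax(avg[i, di], 0)), numeric(1))
    centers[mass < 2 / sqrt(dim(tens$grc)[3])] <- NA_real_
    list(ant = ant, rcf = rcf, centers = centers)
  })
  persist(cbind(labels$ant, center_time_s = labels$centers), "grc_labels.csv")
  persist(labels$rcf, "cf_labels.csv")
  report$classification <- list(
    frac_anticipatory_grc = mean(labels$ant$anticipatory),
    frac_reward_cf = mean(labels$rcf$reward_cf))

  plast <- stage("plasticity", {
    pp <- do.call(plasticity_params, cfg$plasticity)
    inc <- select_included_cfs(tens$cf, pp)
    if (!any(inc)) stop("no teaching signal: no CF passes inclusion")
    spikes <- reward_spike_events(spk$events[inc], tb, pp)
    s_full <- logistic_scale(cond$grc_z, pp$logistic_scale_percentile)
    wtrue <- compute_session_weights(tens$grc, spikes, pp, s_full)
    rate_inc <- structure(unclass(tens$cf)[inc, , , drop = FALSE],
                          time_s = tensor_time(tens$cf),
                          trial_ids = attr(tens$cf, "trial_ids"),
                          class = c("aligned_tensor", "array"))
    wltp <- compute_ltp_adjusted_weights(tens$grc, rate_inc, spikes, pp,
                                         s_full, seed = cfg$seed)
    wsets <- list(
      true = wtrue, ltp_adjusted = wltp,
      time_shuffled = control_weights(tens$grc, spikes, "time_shuffled",
                                      cfg$seed, pp, logistic_s = s_full),
      reordered = control_weights(tens$grc, spikes, "reordered", cfg$seed,
                                  pp, true_weights = wtrue),
      uniform = control_weights(tens$grc, spikes, "uniform", cfg$seed, pp))
    list(params = pp, included = inc, spikes = spikes, wsets = wsets)
  })
  wdf <- do.call(rbind, lapply(plast$wsets, function(w)
    data.frame(grc_id = seq_along(w$session_vector),
               weight = w$session_vector, provenance = w$provenance)))
  persist(wdf, "weights.csv")
  if (!is.null(odir))
    jsonlite::write_json(unclass(plast$params),
                         file.path(odir, "plasticity_params.json"),
                         auto_unbox = TRUE, digits = NA)
  ok <- is.finite(labels$centers) &
    is.finite(plast$wsets$true$grc_ltd_magnitude)
  report$plasticity <- list(
    n_included_cf = sum(plast$included),
    ltd_center_spearman = if (sum(ok) > 2)
      unname(cor(labels$centers[ok], plast$wsets$true$grc_ltd_magnitude[ok],
                 method = "spearman")) else NA_real_)

  readouts <- stage("readout", {
    delay_win <- c(-delay, 0)
    cmp <- compare_readouts(tens$grc, plast$wsets, delay_win,
                            decoder_seed = cfg$seed)
    dec_delay <- decode_time_cv(tens$grc, delay_win,
                                folds = cfg$analysis$decode_folds,
                                seed = cfg$seed)
    prw <- cfg$analysis$post_reward_window_s
    dec_post <- tryCatch({
      post_tens <- align_to_trials(cond$grc_z, ses$frame_times_s, tb,
                                   "reward", prw, subset = "rewarded")
      decode_time_cv(post_tens, folds = cfg$analysis$decode_folds,
                     seed = cfg$seed)
    }, error = function(e) NULL)
    list(table = cmp, dec_delay = dec_delay, dec_post = dec_post)
  })
  persist(readouts$table, "readout_metrics.csv")
  report$readout <- list(
    comparison = readouts$table,
    decode_delay_r2 = readouts$dec_delay$r2,
    decode_delay_mae_ms = readouts$dec_delay$mae_ms,
    decode_post_reward_r2 = if (!is.null(readouts$dec_post))
      readouts$dec_post$r2 else NA_real_)

  if (!is.null(odir))
    jsonlite::write_json(report, file.path(odir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  report
}
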