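#' Simulate a complete synthetic GrC-CF session
#'
#' Runs [simulate_trials()], [simulate_grc_population()] and
#' [simulate_cf_population()] under one config and bundles the results.
#' Identical configs (including seed) give bit-identical sessions.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_session` with elements `config`, `trials`
#'   (trial table), `behavior` (200 Hz streams), `frame_times_s`, `grc`,
#'   `cf`, `duration_s`.
#' @examples
#' ses <- simulate_session(synth_config(n_grc = 10, n_cf = 3, n_trials = 5,
#'                                      seed = 11))
#' dim(ses$grc$z)
#' @export
simulate_session <- function(config) {
  tr <- simulate_trials(config)
  grc <- simulate_grc_population(config, tr)
  cf <- simulate_cf_population(config, tr)
  out <- list(config = config, trials = tr$trials, behavior = tr$behavior,
              frame_times_s = grc$frame_times_s, grc = grc, cf = cf,
              duration_s = tr$duration_s)
  class(out) <- "synth_session"
  out
}

#' @export
print.synth_session <- function(x, ...) {
  cat("<synth_session> ", x$config$expertise, ", ",
      nrow(x$grc$z), " GrCs x ", ncol(x$grc$z), " frames, ",
      nrow(x$cf$z), " CFs, ", nrow(x$trials), " trials (",
      sum(x$trials$omission), " omissions), ",
      round(x$duration_s), " s @ ", x$config$frame_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic session as plain-text files
#'
#' The on-disk layout is one directory holding delimited matrices
#' (`grc_F.csv`, `grc_z.csv`, `cf_F.csv`, `cf_z.csv`; cells x frames),
#' `frame_times.csv`, the behavior stream (`behavior.csv`), the trial table
#' (`trials.csv`), ground-truth tables (`grc_truth.csv`, `cf_truth.csv`,
#' `cf_events_true.csv` with columns `cell`, `time_s`) and a JSON sidecar of
#' the generating config (`config.json`).
#'
#' @param session a `synth_session`.
#' @param dir output directory (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` returns a
#'   `synth_session` (numerically equal to the written one up to text
#'   round-off; written at full precision).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synth_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(data.table::as.data.table(x),
                                          file.path(dir, f))
  fw(session$grc$raw, "grc_F.csv"); fw(session$grc$z, "grc_z.csv")
  fw(session$cf$raw, "cf_F.csv"); fw(session$cf$z, "cf_z.csv")
  fw(data.frame(t = session$frame_times_s), "frame_times.csv")
  fw(session$behavior, "behavior.csv")
  fw(session$trials, "trials.csv")
  fw(session$grc$truth, "grc_truth.csv")
  fw(session$cf$truth, "cf_truth.csv")
  ev <- session$cf$events_true
  fw(data.frame(cell = rep(seq_along(ev), lengths(ev)), time_s = unlist(ev)),
     "cf_events_true.csv")
  cfg <- unclass(session$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  fr <- function(f) data.table::fread(file.path(dir, f))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$bleach_params <- as.list(cfg$bleach_params)
  config <- do.call(synth_config, cfg[setdiff(names(cfg), character())])
  ft <- fr("frame_times.csv")$t
  evtab <- fr("cf_events_true.csv")
  cf_truth <- as.data.frame(fr("cf_truth.csv"))
  events <- lapply(seq_len(nrow(cf_truth)),
                   function(i) evtab$time_s[evtab$cell == i])
  grc <- list(z = as.matrix(fr("grc_z.csv")), raw = as.matrix(fr("grc_F.csv")),
              frame_times_s = ft, truth = as.data.frame(fr("grc_truth.csv")))
  dimnames(grc$z) <- dimnames(grc$raw) <- NULL
  cf <- list(z = as.matrix(fr("cf_z.csv")), raw = as.matrix(fr("cf_F.csv")),
             events_true = events, frame_times_s = ft, truth = cf_truth)
  dimnames(cf$z) <- dimnames(cf$raw) <- NULL
  class(grc) <- "synth_grc"; class(cf) <- "synth_cf"
  behavior <- as.data.frame(fr("behavior.csv"))
  trials <- as.data.frame(fr("trials.csv"))
  out <- list(config = config, trials = trials, behavior = behavior,
              frame_times_s = ft, grc = grc, cf = cf,
              duration_s = max(ft))
  class(out) <- "synth_session"
  out
}
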