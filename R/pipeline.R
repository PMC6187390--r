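#' Pipeline configuration
#'
#' Bundles and validates the configuration of every pipeline stage. Unknown
#' keys are rejected so that config-file typos fail loudly.
#'
#' @param dialect Raw-CSV column mapping from [csv_dialect()].
#' @param epoch_seconds Epoch length in seconds (default 5).
#' @param interval_seconds AI interval in seconds (default 60).
#' @param cut_points Activity-level cut points from [level_thresholds()].
#' @param sleep A [sleep_config()].
#' @param anchor Analysis-day anchor clock time (default `"12:00:00"`).
#' @param allow_partial Process incomplete analysis days (default FALSE;
#'   regularity and daily summaries assume 24 h of data).
#' @param post_wake Post-wake capability windows for [summarize_day()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(dialect = csv_dialect(),
                            epoch_seconds = 5,
                            interval_seconds = 60,
                            cut_points = level_thresholds(),
                            sleep = sleep_config(),
                            anchor = "12:00:00",
                            allow_partial = FALSE,
                            post_wake = list(c(x_hours = 3, min_level = 3))) {
  stopifnot(inherits(sleep, "sleep_config"))
  cfg <- list(dialect = dialect,
              epoch_seconds = epoch_seconds,
              interval_seconds = interval_seconds,
              cut_points = level_thresholds(cut_points),
              sleep = sleep,
              anchor = anchor,
              allow_partial = isTRUE(allow_partial),
              post_wake = post_wake)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build a pipeline_config from a plain (e.g. YAML-decoded) list
#'
#' @param x Named list with any subset of the keys of [pipeline_config()];
#'   `sleep` and `dialect` may themselves be plain lists.
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$sleep) && !inherits(x$sleep, "sleep_config")) {
    x$sleep <- do.call(sleep_config, x$sleep)
  }
  if (!is.null(x$dialect)) x$dialect <- do.call(csv_dialect, x$dialect)
  if (!is.null(x$cut_points)) x$cut_points <- unlist(x$cut_points)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline on a raw acceleration file
#'
#' Raw CSV -> epoch sigmas -> minute AI -> per-day activity levels, sleep
#' detection, hourly AI -> RI trend -> daily summaries. All intermediates
#' are written as CSV (plus a JSON summary) into `out_dir` so stages can be
#' inspected and re-run independently.
#'
#' @param raw_path Path to a raw `timestamp,x,y,z` CSV, or an in-memory
#'   [triaxial_recording()].
#' @param out_dir Output directory, created if needed.
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage row counts to stderr (default TRUE).
#' @return Invisibly, a list with elements `minutes`, `levels`, `states`,
#'   `periods`, `hourly` (24 x D matrix), `ri`, `summaries`.
#' @export
run_pipeline <- function(raw_path, out_dir, config = pipeline_config(),
                         verbose = TRUE) {
  config <- as_pipeline_config(config)
  log <- function(...) if (verbose) message("[actimetry] ", sprintf(...))

  rec <- if (inherits(raw_path, "triaxial_recording")) raw_path else {
    read_raw_csv(raw_path, config$dialect)
  }
  log("raw: %d samples at %g Hz", length(rec), rec$sample_rate_hz)
  sig <- epoch_sigma(rec, config$epoch_seconds)
  minutes <- minute_ai(sig, config$interval_seconds)
  log("minute AI: %d minutes", nrow(minutes))
  if (nrow(minutes) == 0) {
    stop("no complete minutes in the input", call. = FALSE)
  }

  days <- partition_days(minutes, "minute_start", config$anchor)
  use <- if (config$allow_partial) rep(TRUE, nrow(days)) else days$complete
  if (!any(use)) {
    stop("no complete analysis day in the input (use allow_partial to override)",
         call. = FALSE)
  }
  days <- days[use, ]
  log("analysis days: %d", nrow(days))

  per_day <- lapply(seq_len(nrow(days)), function(i) {
    m <- days$data[[i]]
    st <- detect_sleep_states(m, config$sleep)
    pd <- merge_sleep_periods(st, config$sleep)
    hv <- hourly_ai(m, days$start[i], allow_partial = config$allow_partial)
    list(states = st, periods = pd, hourly = hv)
  })
  hourly <- vapply(per_day, `[[`, numeric(24), "hourly")
  colnames(hourly) <- as.character(days$day_label)
  ri <- ri_trend(hourly)

  summaries <- do.call(rbind, lapply(seq_len(nrow(days)), function(i) {
    summarize_day(days$data[[i]], per_day[[i]]$states,
                  per_day[[i]]$periods, ri = ri$ri_day[i],
                  cut_points = config$cut_points,
                  post_wake = config$post_wake)
  }))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_states <- do.call(rbind, lapply(per_day, `[[`, "states"))
  levels_tbl <- tibble(
    minute_start = ts_format_ms(minutes$minute_start),
    ai = sprintf("%.12g", minutes$ai),
    level = classify_ai(minutes$ai, config$cut_points))
  hourly_long <- tibble(
    day = rep(colnames(hourly), each = 24),
    hour = rep(sprintf("%02d:00:00", c(12:23, 0:11)), ncol(hourly)),
    ai = sprintf("%.12g", as.vector(hourly)))

  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  write_minute_ai_csv(minutes, file.path(out_dir, "minute_ai.csv"))
  wcsv(levels_tbl, "levels.csv")
  wcsv(tibble(minute_start = ts_format_ms(all_states$minute_start),
              ai = sprintf("%.12g", all_states$ai),
              state = all_states$state), "sleep_states.csv")
  periods_all <- do.call(rbind, lapply(seq_len(nrow(days)), function(i) {
    p <- per_day[[i]]$periods
    if (nrow(p) == 0) return(NULL)
    tibble(day = as.character(days$day_label[i]),
           onset = ts_format_ms(p$onset), offset = ts_format_ms(p$offset),
           duration_min = p$duration_min,
           quality = sprintf("%.6g", p$quality))
  }))
  if (is.null(periods_all)) {
    periods_all <- tibble(day = character(), onset = character(),
                          offset = character(), duration_min = integer(),
                          quality = character())
  }
  wcsv(periods_all, "sleep_periods.csv")
  wcsv(hourly_long, "hourly_ai.csv")
  wcsv(transform(ri, ri_day = sprintf("%.6g", ri_day),
                 ri_week = sprintf("%.6g", ri_week)), "ri.csv")
  wcsv(summaries, "daily_summary.csv")
  jsonlite::write_json(summaries, file.path(out_dir, "daily_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  log("summaries: %d day(s) written to %s", nrow(summaries), out_dir)

  invisible(list(minutes = minutes, levels = levels_tbl,
                 states = all_states, periods = periods_all,
                 hourly = hourly, ri = ri, summaries = summaries))
}
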