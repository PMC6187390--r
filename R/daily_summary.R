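#' Activity performed shortly after waking
#'
#' Hours spent at or above a given activity level within the `x_hours`
#' following a wake time — a capability measure: e.g. the time spent at
#' moderate-or-higher activity within 3 h of waking from the main sleep can
#' reflect cardiopulmonary condition.
#'
#' @param minutes Minute-AI tibble covering the window.
#' @param wake Wake timestamp (POSIXct or ISO string), typically the offset
#'   of the day's main sleep period.
#' @param x_hours Length of the post-wake window in hours (> 0).
#' @param min_level Minimum level code (0-4) to count.
#' @param cut_points AI cut points from [level_thresholds()].
#' @return Hours (<= `x_hours`) at level >= `min_level` inside
#'   `[wake, wake + x_hours)`. Warns if the series ends before the window
#'   does (the window is then truncated).
#' @export
post_wake_activity <- function(minutes, wake, x_hours, min_level,
                               cut_points = level_thresholds()) {
  if (x_hours <= 0) stop("x_hours must be positive", call. = FALSE)
  w <- as.numeric(ts_parse(wake))
  t <- as.numeric(minutes$minute_start)
  sel <- t >= w - 1e-6 & t < w + x_hours * 3600 - 1e-6
  if (nrow(minutes) == 0 || max(t) + 60 < w + x_hours * 3600 - 1e-6) {
    warning("post-wake window extends beyond the series; truncated",
            call. = FALSE)
  }
  if (!any(sel)) return(0)
  sum(classify_ai(minutes$ai[sel], cut_points) >= min_level) / 60
}

#' Daily monitoring summary
#'
#' Assembles the per-day parameter set used for activity-based monitoring:
#' \describe{
#'   \item{t_ai}{total AI of the day — sum of all 1440 minute AIs;}
#'   \item{d_ri}{day-to-day Regularity Index against the previous day
#'     (supplied by the caller, `NA` when unavailable);}
#'   \item{sl_t}{sleep hours — total minutes across all detected sleep
#'     periods (naps included) / 60;}
#'   \item{sl_q}{sleep quality — mean minute AI over the sleep periods
#'     (lower = better);}
#'   \item{t_<level>}{hours spent at each of the five activity levels;}
#'   \item{a<x>_t_<level>}{hours at level >= the given code within x hours
#'     after waking from the main (longest) sleep period.}
#' }
#'
#' @param minutes Minute-AI tibble for one complete noon-to-noon day
#'   (1440 rows).
#' @param states Matching output of [detect_sleep_states()].
#' @param periods Output of [merge_sleep_periods()] for the same day.
#' @param ri Day-to-day RI of this day versus the previous one, or `NA`.
#' @param cut_points AI cut points from [level_thresholds()].
#' @param post_wake List of `c(x_hours, min_level)` pairs to evaluate via
#'   [post_wake_activity()] anchored at the main sleep offset; default the
#'   moderate-within-3-h capability measure.
#' @return One-row tibble.
#' @export
summarize_day <- function(minutes, states, periods, ri = NA_real_,
                          cut_points = level_thresholds(),
                          post_wake = list(c(x_hours = 3, min_level = 3))) {
  if (nrow(states) != nrow(minutes) ||
      any(abs(as.numeric(states$minute_start) -
              as.numeric(minutes$minute_start)) > 1e-6)) {
    stop("alignment error: states do not match the minute series",
         call. = FALSE)
  }
  lv <- activity_levels()
  dur <- level_durations(minutes, cut_points) / 60
  names(dur) <- paste0("t_", lv$name)

  sleep_min <- sum(periods$duration_min)
  sl_q <- if (sleep_min > 0) {
    sum(periods$quality * periods$duration_min) / sleep_min
  } else NA_real_

  ms <- main_sleep(periods)
  pw <- lapply(post_wake, function(p) {
    x <- unname(p[1]); ml <- unname(p[2])
    if (is.null(ms)) NA_real_ else {
      suppressWarnings(
        post_wake_activity(minutes, ms$offset, x, ml, cut_points))
    }
  })
  names(pw) <- vapply(post_wake, function(p) {
    sprintf("a%g_t_%d", unname(p[1]), as.integer(p[2]))
  }, character(1))

  out <- tibble(
    day_label = as.Date(ts_new(as.numeric(minutes$minute_start[1]))),
    t_ai = sum(minutes$ai),
    d_ri = as.numeric(ri),
    sl_t = sleep_min / 60,
    sl_q = sl_q)
  out <- cbind(out, as_tibble(as.list(dur)), as_tibble(pw))
  as_tibble(out)
}
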