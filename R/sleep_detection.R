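#' Configuration of the two-phase sleep-duration detector
#'
#' Phase I scans the minute-AI series once, left to right, judging each
#' minute asleep or awake from the current AI and a look-ahead count of
#' sub-threshold AIs. Shortly after an awakening inside a sleep episode (the
#' "fuzzy period") a relaxed, higher threshold is used to judge falling back
#' asleep, reflecting that a subject who just woke is likely to fall asleep
#' again. Phase II merges sleep runs separated by short awake gaps, removing
#' spuriously fragmented sleep.
#'
#' The strict threshold default of 0.1 is the minute-AI bound observed for
#' rest/sleep activity; all other constants are structural and configurable.
#'
#' @param sleep_th_strict Strict AI threshold (default 0.1); also the
#'   bootstrap threshold judging the very first minute's state.
#' @param sleep_th_relaxed Relaxed threshold used inside the fuzzy period
#'   (default 0.2; must be >= strict).
#' @param window1_min Look-ahead window (minutes) for the fall-asleep
#'   criterion (default 10).
#' @param sleep_minth Minimum number of sub-threshold AIs in `window1_min`
#'   to fall asleep (default 8).
#' @param window2_min Look-ahead window (minutes) for the wake-up criterion
#'   (default 10).
#' @param wakeup_minth Wake-up requires fewer than this many sub-threshold
#'   AIs in `window2_min` (default 3).
#' @param fuzzy_min Length (minutes) of the fuzzy period after an in-sleep
#'   awakening (default 15).
#' @param merge_gap_min Phase II merges sleep runs separated by awake gaps
#'   shorter than this (minutes, default 30).
#' @return A validated list of class `sleep_config`.
#' @export
sleep_config <- function(sleep_th_strict = 0.1, sleep_th_relaxed = 0.2,
                         window1_min = 10, sleep_minth = 8,
                         window2_min = 10, wakeup_minth = 3,
                         fuzzy_min = 15, merge_gap_min = 30) {
  cfg <- list(sleep_th_strict = sleep_th_strict,
              sleep_th_relaxed = sleep_th_relaxed,
              window1_min = as.integer(window1_min),
              sleep_minth = as.integer(sleep_minth),
              window2_min = as.integer(window2_min),
              wakeup_minth = as.integer(wakeup_minth),
              fuzzy_min = as.integer(fuzzy_min),
              merge_gap_min = as.integer(merge_gap_min))
  ints <- unlist(cfg[c("window1_min", "sleep_minth", "window2_min",
                       "wakeup_minth", "fuzzy_min", "merge_gap_min")])
  if (any(is.na(ints)) || any(ints <= 0)) {
    stop("all window/count/gap parameters must be positive integers",
         call. = FALSE)
  }
  if (cfg$sleep_minth > cfg$window1_min ||
      cfg$wakeup_minth > cfg$window2_min) {
    stop("count bounds cannot exceed their look-ahead windows", call. = FALSE)
  }
  if (!(cfg$sleep_th_relaxed >= cfg$sleep_th_strict) ||
      cfg$sleep_th_strict <= 0) {
    stop("need sleep_th_relaxed >= sleep_th_strict > 0", call. = FALSE)
  }
  class(cfg) <- "sleep_config"
  cfg
}

#' Per-minute sleep/awake states (Phase I)
#'
#' Single left-to-right scan over a contiguous minute-AI series. The first
#' minute is AWAKE iff its AI >= the strict threshold. Thereafter:
#' \itemize{
#'   \item previous minute AWAKE: with threshold T (relaxed if within
#'     `fuzzy_min` minutes of a wake-up out of a sleep episode, else strict),
#'     the minute falls asleep iff its AI < T and at least `sleep_minth` of
#'     the next `window1_min` AIs are < T;
#'   \item previous minute SLEEP: the minute wakes iff its AI > the strict
#'     threshold and fewer than `wakeup_minth` of the next `window2_min` AIs
#'     are below it.
#' }
#' AI exactly equal to the threshold keeps the previous state; look-ahead
#' windows exclude the current minute and truncate at the series end.
#'
#' @param minutes Minute-AI tibble (columns `minute_start`, `ai`) at a
#'   constant 60 s stride.
#' @param config A [sleep_config()].
#' @return Tibble with columns `minute_start`, `ai`, `state` (integer, 0 =
#'   awake, 1 = sleep).
#' @export
detect_sleep_states <- function(minutes, config = sleep_config()) {
  stopifnot(inherits(config, "sleep_config"))
  n <- nrow(minutes)
  if (n <= config$window1_min) {
    stop("config error: series shorter than the fall-asleep window",
         call. = FALSE)
  }
  t <- as.numeric(minutes$minute_start)
  if (any(abs(diff(t) - 60) > 1e-6)) {
    stop("minute series must be contiguous at a 60 s stride", call. = FALSE)
  }
  ai <- minutes$ai

  # look-ahead counts of sub-threshold AIs, excluding the current minute
  ahead_count <- function(th, w) {
    cs <- c(0, cumsum(ai < th))
    cs[pmin(n, seq_len(n) + w) + 1] - cs[seq_len(n) + 1]
  }
  n_strict1 <- ahead_count(config$sleep_th_strict, config$window1_min)
  n_relax1 <- ahead_count(config$sleep_th_relaxed, config$window1_min)
  n_strict2 <- ahead_count(config$sleep_th_strict, config$window2_min)

  state <- integer(n)
  state[1] <- if (ai[1] >= config$sleep_th_strict) 0L else 1L
  last_wake <- -Inf  # index of the latest sleep->awake transition
  for (i in 2:n) {
    if (state[i - 1] == 0L) {
      fuzzy <- (i - last_wake) <= config$fuzzy_min
      if (fuzzy) {
        asleep <- ai[i] < config$sleep_th_relaxed &&
          n_relax1[i] >= config$sleep_minth
      } else {
        asleep <- ai[i] < config$sleep_th_strict &&
          n_strict1[i] >= config$sleep_minth
      }
      state[i] <- if (asleep) 1L else 0L
    } else {
      wake <- ai[i] > config$sleep_th_strict &&
        n_strict2[i] < config$wakeup_minth
      state[i] <- if (wake) 0L else 1L
      if (wake) last_wake <- i
    }
  }
  tibble(minute_start = minutes$minute_start, ai = ai, state = state)
}

#' Merge fragmented sleep periods (Phase II)
#'
#' Extracts contiguous sleep runs from a state series and absorbs any awake
#' gap shorter than `merge_gap_min` between two runs, left to right until a
#' fixed point. A subject who wakes briefly during the night perceives one
#' sleep period, not several; merging restores that reading. Each period is
#' annotated with its quality: the mean minute AI over the merged span
#' (lower = calmer = better sleep).
#'
#' @param states Output of [detect_sleep_states()].
#' @param config A [sleep_config()].
#' @return Tibble with one row per sleep period: `onset`, `offset` (POSIXct,
#'   `offset` exclusive), `duration_min`, `quality`.
#' @export
merge_sleep_periods <- function(states, config = sleep_config()) {
  stopifnot(inherits(config, "sleep_config"))
  r <- rle(states$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  s_start <- starts[r$values == 1L]
  s_end <- ends[r$values == 1L]
  if (!length(s_start)) {
    return(tibble(onset = ts_new(numeric()), offset = ts_new(numeric()),
                  duration_min = integer(), quality = numeric()))
  }
  # left-to-right absorption of short awake gaps; chain merges allowed
  m_start <- s_start[1]; m_end <- s_end[1]
  out_s <- integer(); out_e <- integer()
  for (k in seq_along(s_start)[-1]) {
    gap <- s_start[k] - m_end - 1
    if (gap < config$merge_gap_min) {
      m_end <- s_end[k]
    } else {
      out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
      m_start <- s_start[k]; m_end <- s_end[k]
    }
  }
  out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
  t <- as.numeric(states$minute_start)
  tibble(
    onset = ts_new(t[out_s]),
    offset = ts_new(t[out_e] + 60),
    duration_min = out_e - out_s + 1L,
    quality = mapply(function(a, b) mean(states$ai[a:b]), out_s, out_e))
}

#' Main sleep period of a day
#'
#' The longest detected sleep period; ties are broken in favour of the later
#' onset.
#'
#' @param periods Tibble from [merge_sleep_periods()].
#' @return One-row tibble, or `NULL` when no sleep period exists.
#' @export
main_sleep <- function(periods) {
  if (is.null(periods) || nrow(periods) == 0) return(NULL)
  best <- order(periods$duration_min, as.numeric(periods$onset),
                decreasing = TRUE)[1]
  periods[best, ]
}
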