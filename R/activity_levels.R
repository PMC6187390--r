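#' The five physical-activity levels
#'
#' Minute AI values map onto five ordered activity levels, coded 0 (rest or
#' sleep) through 4 (vigorous).
#'
#' @return Tibble with columns `code` (integer 0-4) and `name`.
#' @export
activity_levels <- function() {
  tibble(code = 0:4,
         name = c("rest_sleep", "sedentary", "light", "moderate", "vigorous"))
}

#' Default AI cut points between activity levels
#'
#' The default minute-AI cut points are 0.1 (rest/sleep | sedentary),
#' 0.5 (sedentary | light), 2.0 (light | moderate) and 4.0
#' (moderate | vigorous).
#'
#' @param cut_points Strictly ascending positive numeric vector of length 4.
#' @return Validated numeric vector of cut points.
#' @export
level_thresholds <- function(cut_points = c(0.1, 0.5, 2.0, 4.0)) {
  if (length(cut_points) != 4 || any(!is.finite(cut_points)) ||
      any(cut_points <= 0) || is.unsorted(cut_points, strictly = TRUE)) {
    stop("cut_points must be 4 strictly ascending positive numbers",
         call. = FALSE)
  }
  cut_points
}

#' Classify minute AI values into activity levels
#'
#' Levels are assigned by lower-inclusive, half-open intervals:
#' `[0, 0.1)` rest/sleep, `[0.1, 0.5)` sedentary, `[0.5, 2)` light,
#' `[2, 4)` moderate, `[4, Inf)` vigorous. A value exactly on a cut point
#' belongs to the upper level, so the partition is total.
#'
#' @param ai Non-negative numeric vector of minute AI values.
#' @param cut_points Cut points from [level_thresholds()].
#' @return Integer vector of level codes 0-4.
#' @export
classify_ai <- function(ai, cut_points = level_thresholds()) {
  if (any(!is.finite(ai)) || any(ai < 0)) {
    stop("data error: AI values must be finite and >= 0", call. = FALSE)
  }
  cut_points <- level_thresholds(cut_points)
  findInterval(ai, cut_points)
}

#' Minutes spent at each activity level
#'
#' Tallies per-minute classifications over a minute-AI series; the five
#' counts always sum to the series length.
#'
#' @param minutes Minute-AI tibble (columns `minute_start`, `ai`).
#' @param cut_points Cut points from [level_thresholds()].
#' @return Named numeric vector of minutes per level, names
#'   `rest_sleep` ... `vigorous`.
#' @export
level_durations <- function(minutes, cut_points = level_thresholds()) {
  lv <- activity_levels()
  if (nrow(minutes) == 0) {
    return(stats::setNames(numeric(5), lv$name))
  }
  code <- classify_ai(minutes$ai, cut_points)
  stats::setNames(as.numeric(tabulate(code + 1L, nbins = 5L)), lv$name)
}

#' Reference AI ranges for 14 activities of daily living
#'
#' Published minute-AI statistics (maximum, minimum, mean across subjects)
#' for a 14-activity wear test, with the activity level each mean falls in
#' under the default cut points. Shipped as a documentation and test fixture;
#' classification itself uses only [classify_ai()].
#'
#' Note the empirical ranges of neighbouring activities overlap (e.g. the
#' downstairs-walk maximum exceeds the vigorous cut) — classification is per
#' minute by AI value alone.
#'
#' @return Tibble with columns `activity`, `level` (code 0-4), `max`, `min`,
#'   `mean`.
#' @export
adl_reference <- function() {
  tibble(
    activity = c("rest_sleeping", "sit_watching_tv", "sit_reading_newspaper",
                 "sit_web_browsing", "housekeeping", "driving",
                 "walking_no_hand_swing", "walking_hand_swing",
                 "downstairs_no_hand_swing", "downstairs_hand_swing",
                 "upstairs_no_hand_swing", "upstairs_hand_swing",
                 "jogging_no_hand_swing", "jogging_hand_swing"),
    level = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L),
    max = c(0.096975, 0.345286, 0.466089, 0.12198, 1.604074, 1.378413,
            2.334001, 3.973975, 8.124398, 3.40835, 2.602795, 2.464628,
            12.95352, 7.27138),
    min = c(0.082482, 0.092849, 0.090514, 0.100102, 0.829076, 0.976756,
            0.648251, 2.048219, 1.673799, 1.243286, 2.352814, 2.308799,
            4.437786, 4.832407),
    mean = c(0.088523, 0.186028, 0.301787, 0.111355, 1.222838, 1.171664,
             1.59335, 2.541614, 3.890505, 2.415157, 2.515802, 2.393241,
             8.742815, 6.033422))
}
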