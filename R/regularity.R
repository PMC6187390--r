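#' Day-to-day Regularity Index
#'
#' Pearson product-moment correlation between the 24-element hourly AI
#' vectors of two analysis days (noon-first ordering). +1 means the daily
#' activity pattern repeated exactly, 0 uncorrelated, -1 inverted. When
#' either day has zero variance across hours the correlation is undefined
#' and `NA` is returned (never 0, which would falsely signal
#' "uncorrelated").
#'
#' @param prev,cur Numeric vectors of length 24: hourly AI of day i-1 (or
#'   i-7 for the week-to-week index) and of day i, same ordering.
#' @return A single value in `[-1, 1]`, or `NA` if undefined.
#' @export
day_to_day_ri <- function(prev, cur) {
  if (length(prev) != 24 || length(cur) != 24) {
    stop("hourly AI vectors must have length 24", call. = FALSE)
  }
  if (any(!is.finite(prev)) || any(!is.finite(cur))) {
    stop("data error: non-finite hourly AI", call. = FALSE)
  }
  if (sd(prev) == 0 || sd(cur) == 0) return(NA_real_)
  cor(as.numeric(prev), as.numeric(cur))
}

#' Week-to-week Regularity Index
#'
#' Same statistic as [day_to_day_ri()], applied to day i and day i-7.
#'
#' @inheritParams day_to_day_ri
#' @return A single value in `[-1, 1]`, or `NA` if undefined.
#' @export
week_to_week_ri <- function(prev, cur) day_to_day_ri(prev, cur)

#' Regularity Index trend over consecutive days
#'
#' Computes, for each analysis day, the day-to-day RI against the previous
#' calendar day and the week-to-week RI against the same weekday one week
#' earlier, where those days exist in the input.
#'
#' @param hourly 24 x D numeric matrix of hourly AI vectors (rows noon-first,
#'   columns chronological) with unique day labels as column names
#'   (coercible to Date), e.g. from [hourly_matrix()].
#' @return Tibble with columns `day` (Date), `ri_day`, `ri_week` (NA where
#'   no comparison day exists or the RI is undefined).
#' @export
ri_trend <- function(hourly) {
  if (!is.matrix(hourly) || nrow(hourly) != 24) {
    stop("hourly must be a 24 x D matrix", call. = FALSE)
  }
  labels <- as.Date(colnames(hourly))
  if (anyNA(labels)) stop("column names must be dates", call. = FALSE)
  if (anyDuplicated(labels)) {
    stop("data error: duplicate day labels", call. = FALSE)
  }
  if (is.unsorted(labels, strictly = TRUE)) {
    stop("days must be chronologically ordered", call. = FALSE)
  }
  ri_at <- function(i, back) {
    j <- match(labels[i] - back, labels)
    if (is.na(j)) NA_real_ else day_to_day_ri(hourly[, j], hourly[, i])
  }
  d <- length(labels)
  tibble(day = labels,
         ri_day = vapply(seq_len(d), ri_at, numeric(1), back = 1),
         ri_week = vapply(seq_len(d), ri_at, numeric(1), back = 7))
}
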