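#' Magnitude of a tri-axial acceleration sample
#'
#' `sqrt(x^2 + y^2 + z^2)`. Working on the magnitude removes the effect of
#' device orientation before any further processing.
#'
#' @param x,y,z Finite numeric vectors of per-axis acceleration in g.
#' @return Non-negative numeric vector of magnitudes in g.
#' @export
acc_magnitude <- function(x, y, z) {
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("data error: non-finite acceleration value", call. = FALSE)
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Per-epoch standard deviation of acceleration magnitude
#'
#' Splits the recording into non-overlapping epochs of `epoch_seconds`
#' (clock-aligned by default) and computes, within each complete epoch, the
#' population standard deviation (divide by N, not N-1) of the per-sample
#' acceleration magnitudes. Subtracting the epoch mean magnitude removes the
#' 1 g gravity component: over a short epoch the mean of the total
#' acceleration is taken as gravity, so sigma measures net body movement.
#'
#' At the default 20 Hz and 5 s epochs each sigma is computed from N = 100
#' samples. Trailing / leading partial epochs are discarded, not padded.
#'
#' @param rec A [triaxial_recording()].
#' @param epoch_seconds Epoch length in seconds (default 5). Must give an
#'   integer number of samples N >= 2.
#' @param align `"clock"` (epochs start at multiples of `epoch_seconds` on
#'   the clock, so they tile minutes exactly) or `"recording"` (epochs start
#'   at the first sample).
#' @return Tibble with columns `epoch_start` (POSIXct) and `sigma` (g), with
#'   attributes `epoch_seconds` and `n_samples_per_epoch`.
#' @export
epoch_sigma <- function(rec, epoch_seconds = 5,
                        align = c("clock", "recording")) {
  stopifnot(inherits(rec, "triaxial_recording"))
  align <- match.arg(align)
  if (length(rec) == 0) stop("recording is empty", call. = FALSE)
  n_per <- epoch_seconds * rec$sample_rate_hz
  if (abs(n_per - round(n_per)) > 1e-6 || round(n_per) < 2) {
    stop("config error: epoch_seconds x sample rate must be an integer >= 2",
         call. = FALSE)
  }
  n_per <- as.integer(round(n_per))
  t <- as.numeric(rec$start_time) + (seq_len(length(rec)) - 1) / rec$sample_rate_hz
  origin <- if (align == "clock") 0 else t[1]
  id <- floor((t - origin + 1e-6) / epoch_seconds)
  A <- acc_magnitude(rec$x, rec$y, rec$z)

  r <- rle(id)
  ends <- cumsum(r$lengths)
  csA <- cumsum(A)
  sumA <- csA[ends] - c(0, csA[ends[-length(ends)]])
  # two-pass variance: centre within each epoch first, so a perfectly still
  # epoch yields sigma exactly 0 (no cancellation error)
  mu_all <- rep.int(sumA / r$lengths, r$lengths)
  csD <- cumsum((A - mu_all)^2)
  ssq <- csD[ends] - c(0, csD[ends[-length(ends)]])
  keep <- r$lengths == n_per
  sigma <- sqrt(ssq[keep] / n_per)
  out <- tibble(epoch_start = ts_new(origin + r$values[keep] * epoch_seconds),
                sigma = sigma)
  attr(out, "epoch_seconds") <- epoch_seconds
  attr(out, "n_samples_per_epoch") <- n_per
  out
}

#' Minute-wise Activity Index
#'
#' The Activity Index over a time interval is the sum of the per-epoch
#' standard deviations falling in that interval. With the default 5 s epochs
#' and 60 s interval each minute AI is the sum of M = 12 epoch sigmas.
#' Only complete, clock-aligned intervals are emitted.
#'
#' @param sigmas Output of [epoch_sigma()].
#' @param interval_seconds Interval length in seconds (default 60); must be a
#'   positive integer multiple of the epoch length.
#' @return Tibble with columns `minute_start` (POSIXct) and `ai`
#'   (dimensionless, sum of g-valued sigmas), with attribute
#'   `epochs_per_minute` (M).
#' @export
minute_ai <- function(sigmas, interval_seconds = 60) {
  ep <- attr(sigmas, "epoch_seconds")
  if (is.null(ep)) stop("sigmas must come from epoch_sigma()", call. = FALSE)
  m <- interval_seconds / ep
  if (abs(m - round(m)) > 1e-9 || round(m) < 1) {
    stop("config error: interval must be a positive integer multiple of the epoch",
         call. = FALSE)
  }
  m <- as.integer(round(m))
  t <- as.numeric(sigmas$epoch_start)
  if (length(t) && any(abs((t %% interval_seconds) %% ep) > 1e-6 &
                       abs((t %% interval_seconds) %% ep - ep) > 1e-6)) {
    stop("alignment error: epochs do not tile the interval grid", call. = FALSE)
  }
  id <- floor((t + 1e-6) / interval_seconds)
  r <- rle(id)
  ends <- cumsum(r$lengths)
  cs <- cumsum(sigmas$sigma)
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  keep <- r$lengths == m
  out <- tibble(minute_start = ts_new(r$values[keep] * interval_seconds),
                ai = sums[keep])
  attr(out, "epochs_per_minute") <- m
  attr(out, "interval_seconds") <- interval_seconds
  out
}

#' Hourly Activity Index vector of one analysis day
#'
#' Accumulates minute AIs into the 24 hourly totals of one noon-to-noon day,
#' ordered noon first (12:00, 13:00, ..., 11:00). Hourly patterns are the
#' input of the Regularity Index: 1440 minute values per day are reduced to
#' 24 without losing the daily structure.
#'
#' @param minutes Minute-AI tibble (columns `minute_start`, `ai`).
#' @param day_start POSIXct (or ISO string) of the window start, normally a
#'   clock noon.
#' @param allow_partial If FALSE (default), all 1440 minutes of the window
#'   must be present.
#' @return Named numeric vector of length 24 (names `"12:00"` ... `"11:00"`),
#'   with attribute `day_label`.
#' @export
hourly_ai <- function(minutes, day_start, allow_partial = FALSE) {
  s <- as.numeric(ts_parse(day_start))
  t <- as.numeric(minutes$minute_start)
  sel <- t >= s - 1e-6 & t < s + 86400 - 1e-6
  idx <- as.integer(round((t[sel] - s) / 60))
  if (!allow_partial && !identical(sort(idx), 0:1439)) {
    stop("coverage error: day not fully covered by 1440 distinct minutes",
         call. = FALSE)
  }
  hour_idx <- idx %/% 60
  v <- vapply(0:23, function(h) sum(minutes$ai[sel][hour_idx == h]),
              numeric(1))
  names(v) <- sprintf("%02d:00", (12 + 0:23) %% 24)
  attr(v, "day_label") <- as.Date(ts_new(s))
  v
}
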