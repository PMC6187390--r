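#' Tri-axial wrist acceleration recording
#'
#' Container for uniformly sampled tri-axial acceleration in g. Sample
#' timestamps are implied by `start_time + (i - 1) / sample_rate_hz` and are
#' not stored.
#'
#' @param x,y,z Equal-length numeric vectors of acceleration along the three
#'   orthogonal device axes, in g.
#' @param start_time Timestamp (POSIXct or ISO-8601 string) of the first
#'   sample, millisecond precision.
#' @param sample_rate_hz Positive sampling rate in Hz (default 20, the
#'   configuration used for activities-of-daily-living monitoring).
#' @param device_meta Optional named list of device metadata. If it contains
#'   `range_g`, all samples are checked against `[-range_g, range_g]`.
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, start_time,
                               sample_rate_hz = 20,
                               device_meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(x) != length(y) || length(x) != length(z)) {
    stop("x, y, z must have identical length", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y)) ||
                    !all(is.finite(z)))) {
    stop("acceleration samples must all be finite", call. = FALSE)
  }
  if (!is.null(device_meta$range_g)) {
    r <- device_meta$range_g
    if (length(x) && max(abs(c(x, y, z))) > r + 1e-12) {
      stop("samples exceed the declared device range of ±", r, " g",
           call. = FALSE)
    }
  }
  structure(
    list(x = x, y = y, z = z,
         start_time = ts_parse(start_time)[1],
         sample_rate_hz = sample_rate_hz,
         device_meta = device_meta),
    class = "triaxial_recording")
}

#' @export
length.triaxial_recording <- function(x) length(x$x)

#' @export
print.triaxial_recording <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<triaxial_recording> %d samples at %g Hz (%.1f min)\n",
              n, x$sample_rate_hz, n / x$sample_rate_hz / 60))
  cat("  start:", ts_format_ms(x$start_time), "\n")
  invisible(x)
}

#' Sample timestamps of a recording
#'
#' @param rec A [triaxial_recording()].
#' @return POSIXct vector, one timestamp per sample.
#' @export
sample_times <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  ts_new(as.numeric(rec$start_time) +
           (seq_len(length(rec)) - 1) / rec$sample_rate_hz)
}

#' Column dialect for raw acceleration CSV
#'
#' Maps the columns of an arbitrary long-format export onto the canonical
#' `timestamp,x,y,z` layout.
#'
#' @param timestamp,x,y,z Column names in the source file.
#' @param declared_rate_hz Optional nominal sampling rate; if the measured
#'   (median inter-sample) rate deviates from it by more than 1% a warning is
#'   raised and the measured rate is kept.
#' @return A named list usable as the `dialect` argument of [read_raw_csv()].
#' @export
csv_dialect <- function(timestamp = "timestamp", x = "x", y = "y", z = "z",
                        declared_rate_hz = NULL) {
  list(timestamp = timestamp, x = x, y = y, z = z,
       declared_rate_hz = declared_rate_hz)
}

#' Read a raw tri-axial acceleration CSV
#'
#' Expects long-format rows of one sample each. Rows are sorted by timestamp;
#' the sampling rate is measured as the median inter-sample interval.
#'
#' @param path Path to the CSV file.
#' @param dialect Column mapping from [csv_dialect()].
#' @return A [triaxial_recording()].
#' @export
read_raw_csv <- function(path, dialect = csv_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(dialect[c("timestamp", "x", "y", "z")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("data error: raw file contains no samples", call. = FALSE)
  }
  t <- as.numeric(ts_parse(df[[dialect$timestamp]]))
  ord <- order(t)
  t <- t[ord]
  if (nrow(df) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop("data error: duplicated timestamps after sorting", call. = FALSE)
    }
    # timestamps carry millisecond precision; snap the median interval to
    # microseconds so 50 ms reads back as exactly 20 Hz
    rate <- 1e6 / round(median(dt) * 1e6)
  } else {
    rate <- dialect$declared_rate_hz %||% 20
  }
  if (!is.null(dialect$declared_rate_hz) &&
      abs(rate - dialect$declared_rate_hz) / dialect$declared_rate_hz > 0.01) {
    warning(sprintf(
      "measured rate %.4g Hz deviates >1%% from declared %.4g Hz; using measured",
      rate, dialect$declared_rate_hz), call. = FALSE)
  }
  triaxial_recording(df[[dialect$x]][ord], df[[dialect$y]][ord],
                     df[[dialect$z]][ord],
                     start_time = ts_new(t[1]), sample_rate_hz = rate)
}

#' Write a recording as canonical raw CSV
#'
#' Header `timestamp,x,y,z`, ISO-8601 timestamps with milliseconds, values in
#' g at full precision (round-trips through [read_raw_csv()] to better than
#' 1e-9 g).
#'
#' @param rec A [triaxial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  lines <- "timestamp,x,y,z"
  if (length(rec)) {
    ts <- ts_format_ms(sample_times(rec))
    lines <- c(lines, paste(ts,
                            sprintf("%.12g", rec$x),
                            sprintf("%.12g", rec$y),
                            sprintf("%.12g", rec$z), sep = ","))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write a minute-wise Activity Index CSV
#'
#' Canonical columns `minute_start,ai` (ISO-8601; dimensionless g-based AI).
#'
#' @param path File path.
#' @return `read_minute_ai_csv()`: tibble with columns `minute_start`
#'   (POSIXct) and `ai`.
#' @export
read_minute_ai_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("minute_start", "ai") %in% names(df))) {
    stop("format error: expected columns minute_start,ai", call. = FALSE)
  }
  tibble(minute_start = ts_parse(df$minute_start), ai = as.numeric(df$ai))
}

#' @param minutes Tibble with columns `minute_start`, `ai`.
#' @rdname read_minute_ai_csv
#' @export
write_minute_ai_csv <- function(minutes, path) {
  out <- data.frame(minute_start = ts_format_ms(minutes$minute_start),
                    ai = sprintf("%.12g", minutes$ai))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-day hourly Activity Index CSV
#'
#' Long format keyed by analysis-day label: columns `day` (date of the
#' window's noon start), `hour` (clock time `HH:MM:SS` of the hour start) and
#' `ai`.
#'
#' @param path File path.
#' @return Tibble with columns `day` (Date), `hour` (character), `ai`.
#' @export
read_hourly_ai_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("day", "hour", "ai") %in% names(df))) {
    stop("format error: expected columns day,hour,ai", call. = FALSE)
  }
  tibble(day = as.Date(df$day), hour = as.character(df$hour),
         ai = as.numeric(df$ai))
}

#' Convert long hourly AI rows to a 24 x D matrix
#'
#' Rows are the 24 hours in noon-first order (12:00, 13:00, ..., 11:00);
#' columns are analysis days, labelled by their noon-start date.
#'
#' @param hourly Tibble as returned by [read_hourly_ai_csv()].
#' @return Numeric 24 x D matrix with day labels as column names.
#' @export
hourly_matrix <- function(hourly) {
  hours <- sprintf("%02d:00:00", c(12:23, 0:11))
  days <- sort(unique(hourly$day))
  m <- matrix(NA_real_, nrow = 24, ncol = length(days),
              dimnames = list(hours, as.character(days)))
  idx_h <- match(substr(hourly$hour, 1, 8), hours)
  if (anyNA(idx_h)) {
    stop("data error: hour values must be on-the-hour clock times",
         call. = FALSE)
  }
  m[cbind(idx_h, match(hourly$day, days))] <- hourly$ai
  if (anyNA(m)) stop("data error: incomplete hourly coverage", call. = FALSE)
  m
}

#' Partition a timestamped series into noon-to-noon analysis days
#'
#' Each sample is assigned to exactly one 24-h window anchored at the clock
#' time `anchor` (default 12:00:00, so that a whole night's sleep falls inside
#' one analysis day). The day label is the calendar date of the window's
#' start, so "9 May" covers 9 May 12:00 through 10 May 11:59:59.
#'
#' @param data Data frame with a POSIXct time column, sorted by time.
#' @param time_col Name of the time column (default `"minute_start"`).
#' @param anchor Clock time of the window start, `"HH:MM:SS"`.
#' @return Tibble with one row per window: `day_label` (Date), `start`, `end`
#'   (POSIXct, `end` exclusive), `n` (samples), `complete` (logical; TRUE when
#'   the window is fully covered at the series' own sampling stride), and a
#'   `data` list-column holding each window's sub-series.
#' @export
partition_days <- function(data, time_col = "minute_start",
                           anchor = "12:00:00") {
  if (!time_col %in% names(data)) {
    stop("no column '", time_col, "' in data", call. = FALSE)
  }
  if (nrow(data) == 0) {
    return(tibble(day_label = as.Date(character()),
                  start = ts_new(numeric()), end = ts_new(numeric()),
                  n = integer(), complete = logical(), data = list()))
  }
  t <- as.numeric(ts_parse(data[[time_col]]))
  if (is.unsorted(t)) stop("series must be sorted by time", call. = FALSE)
  off <- clock_seconds(anchor)
  win_start <- floor((t - off) / 86400) * 86400 + off
  stride <- if (length(t) > 1) median(diff(t)) else NA_real_
  starts <- sort(unique(win_start))
  rows <- lapply(starts, function(s) {
    sel <- win_start == s
    n <- sum(sel)
    complete <- if (is.na(stride)) FALSE else {
      expected <- round(86400 / stride)
      n == expected && abs(min(t[sel]) - s) < stride
    }
    tibble(day_label = as.Date(ts_new(s)),
           start = ts_new(s), end = ts_new(s + 86400),
           n = n, complete = complete,
           data = list(as_tibble(data[sel, , drop = FALSE])))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
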