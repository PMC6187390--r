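# Internal time helpers. All clock arithmetic is done on numeric seconds
# since the epoch with timestamps held in UTC: the analysis day is a clock
# convention, not a civil-time one, so DST must never move a window edge.

.actimetry_tz <- "UTC"

ts_parse <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = .actimetry_tz)
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M:%OS",
                            tz = .actimetry_tz)
  }
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp(s), expected ISO-8601 such as ",
         "2018-05-09T12:00:00.000", call. = FALSE)
  }
  out
}

ts_new <- function(seconds) {
  as.POSIXct(seconds, origin = "1970-01-01", tz = .actimetry_tz)
}

# ISO-8601 with exact millisecond field (format %OS3 truncates, so the
# millisecond part is assembled by hand with carry).
ts_format_ms <- function(t) {
  tn <- as.numeric(t)
  ms <- round((tn - floor(tn)) * 1000)
  carry <- ms >= 1000
  ms[carry] <- ms[carry] - 1000
  secs <- floor(tn) + as.numeric(carry)
  paste0(format(ts_new(secs), "%Y-%m-%dT%H:%M:%S"), sprintf(".%03d", ms))
}

# Seconds-from-midnight of a clock time given as "HH:MM" or "HH:MM:SS".
clock_seconds <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) < 2 || length(p) > 3 || anyNA(p)) {
      stop("clock time must be 'HH:MM' or 'HH:MM:SS', got malformed value",
           call. = FALSE)
    }
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}
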