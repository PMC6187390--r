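# Shared fixtures. Everything is generated in code; the only file fixture is
# the published one-week hourly AI table under inst/extdata.

noon <- function(date = "2018-05-09") {
  as.POSIXct(paste0(date, " 12:00:00"), tz = "UTC")
}

# constant-orientation motionless recording
constant_recording <- function(minutes = 1, rate = 20, g = c(0, 0, 1),
                               start = noon()) {
  n <- minutes * 60 * rate
  triaxial_recording(rep(g[1], n), rep(g[2], n), rep(g[3], n),
                     start_time = start, sample_rate_hz = rate)
}

random_recording <- function(minutes = 1, rate = 20, sd = 0.1,
                             start = noon()) {
  n <- minutes * 60 * rate
  triaxial_recording(rnorm(n, 0, sd), rnorm(n, 0.2, sd), rnorm(n, 1, sd),
                     start_time = start, sample_rate_hz = rate)
}

# uniformly random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

rotate_recording <- function(rec, rot) {
  m <- rot %*% rbind(rec$x, rec$y, rec$z)
  triaxial_recording(m[1, ], m[2, ], m[3, ], start_time = rec$start_time,
                     sample_rate_hz = rec$sample_rate_hz)
}

minute_series <- function(ai, start = noon()) {
  tibble::tibble(
    minute_start = start + 60 * (seq_along(ai) - 1),
    ai = ai)
}

week_fixture_path <- function() {
  system.file("extdata", "hourly_ai_week.csv", package = "actimetry")
}

# RI row of the published worked example (frozen; reproduced by the tests)
week_fixture_ri <- c(0.7078, 0.8386, 0.6484, 0.1430, 0.1105, 0.4395)

# one day with planted sleep; times are minutes after noon
planted_sleep_schedule <- function(sleep_ai = 0.05, wake_ai = 1.2,
                                   onset_min = 660, length_min = 480) {
  behavior_schedule(tibble::tibble(
    state = c("wake", "sleep", "wake"),
    duration_min = c(onset_min, length_min, 1440 - onset_min - length_min),
    sigma = c(wake_ai, sleep_ai, wake_ai) / 12))
}

# full-rate one-day simulated pipeline products, computed once per session
day20_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- preset_schedules()$fragmented_sleep
      rec <- simulate_recording(sched, rate_hz = 20, seed = 20180509)
      sig <- epoch_sigma(rec)
      minutes <- minute_ai(sig)
      cache <<- list(rec = rec, sig = sig, minutes = minutes)
    }
    cache
  }
})
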