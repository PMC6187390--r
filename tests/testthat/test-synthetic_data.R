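test_that("schedule validation enforces day tiling and sane targets", {
  expect_error(behavior_schedule(tibble::tibble(
    state = "a", duration_min = 100, sigma = 0.1)), "tile")
  expect_error(behavior_schedule(tibble::tibble(
    state = "a", duration_min = 1440, sigma = -1)), "sigma")
  ok <- behavior_schedule(tibble::tibble(
    state = "a", duration_min = 1440, sigma = 0.1), day_count = 2)
  expect_s3_class(ok, "behavior_schedule")
  expect_equal(ok$day_count, 2L)
})

test_that("an all-zero schedule produces AI = 0 in every minute", {
  sched <- behavior_schedule(tibble::tibble(
    state = "still", duration_min = 1440, sigma = 0))
  rec <- simulate_recording(sched, rate_hz = 4, seed = 1)
  m <- minute_ai(epoch_sigma(rec))
  expect_equal(nrow(m), 1440)
  expect_lt(max(m$ai), 1e-12)  # zero up to magnitude round-off
})

test_that("simulated epoch sigma hits its target across activity levels", {
  # one hour per target; the hour-mean of 720 five-second epoch sigmas
  # estimates the target far inside the per-epoch Monte-Carlo spread
  targets <- c(0.004, 0.05, 0.2, 0.5)
  sched <- behavior_schedule(tibble::tibble(
    state = sprintf("s%d", 1:6),
    duration_min = c(60, 60, 60, 60, 600, 600),
    sigma = c(targets, 0, 0)))
  rec <- simulate_recording(sched, rate_hz = 20, seed = 101)
  sig <- epoch_sigma(rec)
  for (i in seq_along(targets)) {
    block <- sig$sigma[(720 * (i - 1) + 1):(720 * i)]
    expect_lt(abs(mean(block) / targets[i] - 1), 0.02)
    # per-epoch Monte-Carlo spread: nearly all epochs within ±10% at N = 100
    expect_gt(mean(abs(block / targets[i] - 1) <= 0.10), 0.8)
  }
})

test_that("a sigma-0.5 segment gives mean minute AI near 12 x 0.5", {
  sched <- behavior_schedule(tibble::tibble(
    state = "vigorous", duration_min = 1440, sigma = 0.5))
  rec <- simulate_recording(sched, rate_hz = 20, seed = 5)
  m <- minute_ai(epoch_sigma(rec))
  expect_lt(abs(mean(m$ai) / 6 - 1), 0.10)
})

test_that("the same seed reproduces a recording bit-identically", {
  sched <- behavior_schedule(tibble::tibble(
    state = "a", duration_min = 1440, sigma = 0.1))
  r1 <- simulate_recording(sched, rate_hz = 2, seed = 77)
  r2 <- simulate_recording(sched, rate_hz = 2, seed = 77)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$z, r2$z)
  r3 <- simulate_recording(sched, rate_hz = 2, seed = 78)
  expect_false(identical(r1$x, r3$x))
})

test_that("quantisation snaps samples to the 3.90625 mg grid within ±8 g", {
  sched <- behavior_schedule(tibble::tibble(
    state = "a", duration_min = 1440, sigma = 0.3))
  rec <- simulate_recording(sched, rate_hz = 1, quantize = TRUE, seed = 9)
  step <- 16 / 4096
  expect_lt(max(abs(rec$x / step - round(rec$x / step))), 1e-9)
  expect_lte(max(abs(c(rec$x, rec$y, rec$z))), 8)
  expect_equal(rec$device_meta$range_g, 8)
  # quantisation barely perturbs the recovered sigma
  m <- minute_ai(epoch_sigma(rec, epoch_seconds = 60))
  expect_lt(abs(mean(m$ai) / (0.3 * 1) - 1), 0.15)
})

test_that("minute-level shortcut honours segment means, jitter and seeds", {
  sched <- planted_sleep_schedule()
  m0 <- simulate_minute_ai(sched, jitter = 0, seed = 3)
  expect_equal(nrow(m0), 1440)
  expect_equal(sort(unique(m0$ai)), c(0.05, 1.2))
  # sleep minutes all under the 0.1 rest/sleep bound even with jitter
  m <- simulate_minute_ai(sched, seed = 4)
  sleep_idx <- 661:1140
  expect_true(all(m$ai[sleep_idx] < 0.1))
  expect_true(all(m$ai >= 0))
  expect_identical(simulate_minute_ai(sched, seed = 4)$ai, m$ai)
})

test_that("preset catalogue has the advertised planted structure", {
  pres <- preset_schedules()
  expect_setequal(names(pres), c("regular_week", "fragmented_sleep",
                                 "irregular_shift", "fourteen_activities"))

  # fourteen_activities: noiseless minute AIs classify to the source levels
  ref <- adl_reference()
  m14 <- simulate_minute_ai(pres$fourteen_activities, jitter = 0, seed = 1)
  for (i in 1:14) {
    lv <- classify_ai(m14$ai[(3 * (i - 1) + 1):(3 * i)])
    expect_equal(unique(lv), ref$level[i])
  }

  # regular_week: repeating structure gives high day-to-day RI throughout
  mw <- simulate_minute_ai(pres$regular_week, seed = 8)
  days <- partition_days(mw)
  expect_equal(nrow(days), 7)
  expect_true(all(days$complete))
  hv <- vapply(seq_len(7), function(i) hourly_ai(days$data[[i]],
                                                 days$start[i]), numeric(24))
  colnames(hv) <- as.character(days$day_label)
  tr <- ri_trend(hv)
  expect_true(all(tr$ri_day[-1] >= 0.9))

  # fragmented_sleep: sub-merge-gap awakenings leave one main 7-h period
  mf <- simulate_minute_ai(pres$fragmented_sleep, seed = 12)
  pd <- merge_sleep_periods(detect_sleep_states(mf))
  ms <- main_sleep(pd)
  expect_equal(as.numeric(ms$onset - noon(), units = "mins"), 660,
               tolerance = 10)
  expect_equal(ms$duration_min, 420, tolerance = 15)
})
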