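test_that("raw CSV reading resolves columns, sorts rows and measures the rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z",
               "2018-05-09T12:00:00.000,0,0,1",
               "2018-05-09T12:00:00.050,0,0,1",
               "2018-05-09T12:00:00.100,0,0,1"), path)
  rec <- read_raw_csv(path)
  expect_s3_class(rec, "triaxial_recording")
  expect_length(rec, 3)
  expect_equal(rec$sample_rate_hz, 20)
  expect_equal(rec$z, c(1, 1, 1))

  # permuted columns with a remapped dialect give the identical recording
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("az,ax,when,ay",
               "1,0,2018-05-09T12:00:00.000,0",
               "1,0,2018-05-09T12:00:00.050,0",
               "1,0,2018-05-09T12:00:00.100,0"), path2)
  rec2 <- read_raw_csv(path2, csv_dialect(timestamp = "when", x = "ax",
                                          y = "ay", z = "az"))
  expect_equal(rec2$x, rec$x)
  expect_equal(rec2$y, rec$y)
  expect_equal(rec2$z, rec$z)
  expect_equal(as.numeric(rec2$start_time), as.numeric(rec$start_time))
})

test_that("raw CSV errors: missing columns, duplicate timestamps, rate drift", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y", "2018-05-09T12:00:00.000,0,0"), path)
  expect_error(read_raw_csv(path), "missing column")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z",
               "2018-05-09T12:00:00.000,0,0,1",
               "2018-05-09T12:00:00.000,0,0,1"), path2)
  expect_error(read_raw_csv(path2), "duplicated timestamps")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y,z",
               "2018-05-09T12:00:00.000,0,0,1",
               "2018-05-09T12:00:00.100,0,0,1",
               "2018-05-09T12:00:00.200,0,0,1"), path3)
  expect_warning(rec <- read_raw_csv(path3,
                                     csv_dialect(declared_rate_hz = 20)),
                 "deviates")
  expect_equal(rec$sample_rate_hz, 10)
})

test_that("write_raw_csv emits the canonical layout and round-trips", {
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(triaxial_recording(numeric(), numeric(), numeric(),
                                   start_time = noon()), p0)
  expect_identical(readLines(p0), "timestamp,x,y,z")

  p3 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(constant_recording(minutes = 1 / 240), p3)  # 5 samples
  expect_length(readLines(p3), 6)
  expect_identical(readLines(p3)[1], "timestamp,x,y,z")

  set.seed(42)
  rec <- random_recording(minutes = 10)
  p <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(rec, p)
  back <- read_raw_csv(p)
  expect_length(back, length(rec))
  expect_lt(max(abs(back$x - rec$x), abs(back$y - rec$y),
                abs(back$z - rec$z)), 1e-9)
  expect_equal(back$sample_rate_hz, rec$sample_rate_hz, tolerance = 1e-9)
  expect_equal(as.numeric(back$start_time), as.numeric(rec$start_time),
               tolerance = 1e-3)
})

test_that("recording validation enforces equal lengths, finiteness and range", {
  expect_error(triaxial_recording(1:3, 1:2, 1:3, noon()), "identical length")
  expect_error(triaxial_recording(NA, 0, 0, noon()), "finite")
  expect_error(triaxial_recording(9, 0, 0, noon(),
                                  device_meta = list(range_g = 8)),
               "range")
  expect_error(triaxial_recording(0, 0, 1, noon(), sample_rate_hz = 0),
               "positive")
})

test_that("noon-to-noon partition labels, completeness and boundaries", {
  m <- minute_series(rep(1, 1440))
  parts <- partition_days(m)
  expect_equal(nrow(parts), 1)
  expect_equal(parts$day_label, as.Date("2018-05-09"))
  expect_equal(parts$n, 1440L)
  expect_true(parts$complete)
  expect_equal(format(parts$start, "%H:%M:%S"), "12:00:00")
  expect_equal(as.numeric(parts$end - parts$start, units = "hours"), 24)

  # 36 h starting at midnight: spans two noon-anchored windows, one complete
  m2 <- minute_series(rep(1, 36 * 60),
                      start = as.POSIXct("2018-05-09 00:00:00", tz = "UTC"))
  parts2 <- partition_days(m2)
  expect_equal(nrow(parts2), 2)
  expect_equal(parts2$day_label, as.Date(c("2018-05-08", "2018-05-09")))
  expect_equal(parts2$complete, c(FALSE, TRUE))
  expect_equal(sum(parts2$n), 36 * 60)
})

test_that("partition conserves every sample across windows", {
  set.seed(7)
  n <- 7 * 1440 + 313
  m <- minute_series(runif(n), start = noon() - 3600 * 5)
  parts <- partition_days(m)
  expect_equal(sum(parts$n), n)
  expect_equal(sum(vapply(parts$data, nrow, integer(1))), n)
  # chronological, disjoint
  expect_true(!is.unsorted(as.numeric(parts$start), strictly = TRUE))
  all_times <- do.call(c, lapply(parts$data, function(d) d$minute_start))
  expect_equal(sort(as.numeric(all_times)), as.numeric(m$minute_start))

  expect_equal(nrow(partition_days(minute_series(numeric()))), 0)
})
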