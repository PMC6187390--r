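Package: actimetry
Title: Activity Index Analytics for Wrist-Worn Accelerometer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for raw tri-axial wrist acceleration sampled at
    a fixed rate (default 20 Hz): per-epoch standard deviation of the
    acceleration magnitude, minute-wise and hourly Activity Index (AI),
    five-level physical-activity classification, two-phase sleep-duration
    detection with fragmented-period merging, day-to-day and week-to-week
    Regularity Index (Pearson correlation of hourly AI patterns), and daily
    monitoring summaries (total AI, sleep hours and quality, per-level hours,
    post-wake activity capability). Includes a seeded synthetic-recording
    generator with planted behavioural schedules so the whole pipeline is
    testable without device data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
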