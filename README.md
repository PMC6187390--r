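# actimetry

Analytics for raw tri-axial wrist-worn accelerometer recordings, aimed at
continuous (24 h/day) activity monitoring for digital-health applications:
quantifying physical activity, detecting sleep duration and quality, and
scoring how regular a subject's daily routine is.

## The model

A wrist device samples acceleration along three orthogonal axes at a fixed
rate (default 20 Hz), in units of g. The processing chain is:

1. **Magnitude.** Each sample contributes only its magnitude
   `A_j = sqrt(ax_j² + ay_j² + az_j²)`, which removes the effect of device
   orientation.
2. **Epoch sigma.** Within each non-overlapping 5-s epoch (N = 100 samples
   at 20 Hz) the population standard deviation of the magnitudes is taken:
   `σ = sqrt( (1/N) Σ (A_j − μ)² )`. Over so short a window the mean
   magnitude μ is essentially the 1 g gravity component, so σ measures net
   body movement; a motionless wrist gives σ = 0 at any orientation.
3. **Activity Index.** The minute-wise AI is the sum of the M = 12 epoch
   sigmas in that clock minute: `AI = Σ σ_k`. One noon-to-noon analysis day
   (12:00:00.000 to 11:59:59.950 next day, so a night's sleep falls inside a
   single day) yields 1440 minute AIs.
4. **Activity levels.** Minute AIs classify into five levels by the cut
   points 0.1 / 0.5 / 2.0 / 4.0: rest/sleep (0), sedentary (1), light (2),
   moderate (3), vigorous (4).
5. **Sleep detection.** A two-phase state machine scans the minute AIs:
   Phase I judges each minute asleep/awake from the current AI against a
   threshold (strict 0.1; relaxed 0.2 during the "fuzzy" minutes just after
   an awakening inside a sleep episode) plus a look-ahead count of
   sub-threshold minutes; Phase II merges sleep runs separated by awake gaps
   shorter than 30 min, removing spurious fragmentation.
6. **Regularity Index.** Each day's 1440 minute AIs are accumulated into a
   24-element hourly vector; the RI of day *i* is the Pearson correlation of
   its hourly vector with day *i−1* (day-to-day) or day *i−7*
   (week-to-week). +1 = identical routine, 0 = uncorrelated, −1 = inverted.
7. **Daily summary.** Per day: total AI (`t_ai`), day-to-day RI (`d_ri`),
   sleep hours (`sl_t`), sleep quality (`sl_q`, mean AI while asleep —
   lower is better), hours per activity level, and post-wake capability
   (hours at ≥ a level within x hours of waking from the main sleep).

A seeded synthetic-recording generator (`behavior_schedule()`,
`simulate_recording()`, `simulate_minute_ai()`, `preset_schedules()`) plants
known behavioural structure — sleep blocks, brief awakenings, shift patterns,
a 14-activity reference protocol — so the whole chain is testable without
device data.

## Worked example

```r
library(actimetry)

# a day with a planted 23:00-06:00 night sleep containing two brief
# awakenings, simulated as raw 20 Hz acceleration
rec <- simulate_recording(preset_schedules()$fragmented_sleep, seed = 7)
minutes <- minute_ai(epoch_sigma(rec))       # 1440 minute AIs
states  <- detect_sleep_states(minutes)
periods <- merge_sleep_periods(states)
periods
#> # A tibble: 1 × 4
#>   onset               offset              duration_min quality
#> 1 2018-05-09 23:00:00 2018-05-10 06:00:00          420   0.135

summarize_day(minutes, states, periods)
#>   day_label     t_ai  d_ri  sl_t      sl_q t_rest_sleep t_sedentary  t_light ...
#> 1 2018-05-09 869.1035    NA     7 0.1352765     6.583333           7 10.41667
```

The two planted awakenings (10 and 15 min) are shorter than the 30-min merge
gap, so Phase II returns one 420-min main sleep; its quality 0.135 is pulled
above the sleeping-level AI (≈0.05) by those awake minutes. The day's 24 h
partition into levels (6.58 h rest/sleep + 7 h sedentary + 10.42 h light)
sums to 24.

Computing the RI trend over a bundled one-week hourly AI table:

```r
h <- hourly_matrix(read_hourly_ai_csv(
  system.file("extdata", "hourly_ai_week.csv", package = "actimetry")))
ri_trend(h)$ri_day
#> [1]     NA 0.7078 0.8386 0.6484 0.1430 0.1105 0.4395
```

The dip to ≈0.14 on the fifth and sixth days flags two days whose hourly
activity pattern broke with the preceding routine.

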