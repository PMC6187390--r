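---
title: "Methods: Activity Index, sleep detection and regularity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Activity Index, sleep detection and regularity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimetry)
```

## The measurement model

A wrist-worn MEMS accelerometer reports acceleration along three orthogonal
device axes, in g, at a fixed rate (20 Hz by default — high enough to
resolve activities of daily living while keeping a month of continuous wear
manageable). The raw signal mixes two components: the constant-magnitude
1 g gravity vector, whose projection onto the axes depends on wrist
orientation, and the net acceleration of body movement.

The pipeline removes orientation in two steps. First, only the per-sample
magnitude $A_j = \sqrt{a_{x,j}^2 + a_{y,j}^2 + a_{z,j}^2}$ is retained, so a
fixed rotation of the device leaves everything downstream unchanged (a
property the test suite checks to $10^{-9}$ under random rotations). Second,
within each short epoch the mean magnitude $\mu$ is subtracted: over a 5-s
window the average total acceleration is essentially gravity, so the
population standard deviation

$$\sigma = \sqrt{\tfrac{1}{N}\sum_{j=1}^{N}(A_j-\mu)^2}$$

measures movement only. A perfectly still wrist gives $\sigma = 0$ at any
orientation. $\sigma$ rather than $\sigma^2$ is used because movement
variances are typically far below 1 g²; kinetic energy is proportional to
$\sigma^2$, so $\sigma$ is a monotone energy proxy on a more legible scale.

The **Activity Index** of a time interval is the sum of its epoch sigmas,
$AI = \sum_{k=1}^{M}\sigma_k$. At the defaults (5-s epochs, 1-min interval,
20 Hz) each epoch holds $N = 100$ samples, each minute holds $M = 12$
epochs, and each noon-to-noon analysis day holds 1440 minute AIs.

Deliberate numerical choices:

* the **population** (divide by $N$) standard deviation is used, exactly as
  the defining formula states, not the $N-1$ sample estimator;
* the variance is computed in two passes (centre within the epoch, then sum
  squares); the one-pass moment formula loses all significant digits for a
  still epoch, reporting $\sigma \approx 10^{-8}$ instead of 0;
* epochs are **clock-aligned** (start at multiples of the epoch length),
  so 12 epochs tile each clock minute exactly; recording-aligned epochs are
  available as an option, and misalignments between the epoch and interval
  grids are an error rather than silently re-binned;
* partial epochs and minutes at the recording edges are **dropped**, never
  padded: a sigma over a short window would be biased low and a partial
  minute AI would under-count;
* when a raw CSV is read, the sampling rate is measured as the median
  inter-sample interval snapped to microseconds, so millisecond timestamps
  at 50 ms spacing read back as exactly 20 Hz.

## Analysis days and timestamps

Analysis days run from clock noon to next clock noon, so a typical night's
sleep lies inside one day; the day label is the date of the noon start.
Timestamps are treated as naive local clock time and stored as POSIXct in
UTC: the convention is clock-based, and modelling daylight-saving shifts
would move window edges for no analytic gain. Days with incomplete minute
coverage are flagged, and the regularity and summary stages refuse them
unless explicitly overridden — a 24-h correlation or a per-level hour budget
is not meaningful on partial data. Recording gaps (e.g. device swaps) are
therefore flagged, not imputed.

## Activity levels

Minute AIs map to five ordered levels by the cut points 0.1 / 0.5 / 2.0 /
4.0 (rest/sleep, sedentary, light, moderate, vigorous). The prose
definitions of the bands are ambiguous exactly at the cut points, so the
package uses lower-inclusive half-open intervals — a value exactly on a cut
belongs to the upper level — making the partition total. The bundled
14-activity reference table (`adl_reference()`) documents empirical min/max/
mean AI per activity; its ranges overlap across levels (a downstairs walk
can momentarily exceed the vigorous cut), which is why classification is
done per minute by value, never by activity identity.

## Sleep detection

Phase I is a single left-to-right scan committing one state per minute;
look-ahead windows read future AI values but decisions are never revisited
(re-scoring passes would make the detector's output depend on its own
output, and the single pass already matches planted truth in testing). The
first minute is judged awake iff its AI is at or above the strict threshold
0.1, the empirical rest/sleep bound. Transitions:

* awake → asleep: current AI below threshold $T$, and at least
  `sleep_minth` (8) of the next `window1_min` (10) AIs below $T$;
* asleep → awake: current AI above the strict threshold, and fewer than
  `wakeup_minth` (3) of the next `window2_min` (10) AIs below it.

$T$ is the strict threshold (0.1) normally and the relaxed one (0.2) during
the `fuzzy_min` (15) minutes after a wake-up that ended a sleep episode —
someone who just woke at night falls back asleep under looser criteria.
The relaxed threshold applies only to falling asleep; wake judgments always
use the strict threshold, since the fuzzy rationale concerns returning to
sleep. Comparisons are strict inequalities, so an AI exactly at threshold
keeps the previous state; look-aheads exclude the current minute and
truncate at the series end.

Only the 0.1 bootstrap value is empirically anchored; the remaining
constants are structural defaults, chosen once so that planted sleep on
synthetic days is recovered within the look-ahead window, and exposed in
`sleep_config()`.

Phase II extracts contiguous sleep runs and absorbs awake **gaps** shorter
than `merge_gap_min` (30) between runs, left to right to a fixed point. The
pre-defined duration in the merging rule is read as the gap length, not the
fragment length: merging across short gaps is the reading that removes
fragmented sleep, and it guarantees Phase II never shortens a period nor
increases the period count. A merged period's quality (mean minute AI over
its span) includes the absorbed awake minutes — a restless night scores
worse than an unbroken one of equal length, which is the intended meaning
of the quality measure. The main sleep is the longest period, with ties
broken toward the later onset (the nocturnal candidate in a noon-anchored
day).

## Regularity Index

Each day is reduced to a 24-element hourly AI vector (minute-level patterns
are too high-dimensional and too jittery for stable day-over-day
comparison), and the RI is the **Pearson** product-moment correlation
between two days' vectors. The correlation flavour was an open choice; it
is settled empirically: the package reproduces all six RI values of the
bundled one-week worked example to the printed four decimals with Pearson,
while rank correlation does not come close. Days with zero variance across
hours have no defined correlation and yield `NA` — returning 0 would
fabricate a "totally uncorrelated" verdict. The day-to-day RI of a day
requires its calendar predecessor; the week-to-week RI the same weekday a
week earlier; both are `NA` when the comparison day is absent.

## Daily summary

`t_ai` is the plain sum of the day's 1440 minute AIs, and conservation
holds along the whole chain: epoch sigmas sum to minute AIs sum to hourly
values sum to `t_ai` (checked to $10^{-9}$). `sl_t` counts **all** detected
sleep periods, naps included, because it reports hours in sleep/rest rather
than nocturnal sleep specifically; `sl_q` is the duration-weighted mean AI
across those periods. Per-level hours `t_<level>` partition the 24-h day;
cumulative "at or above level" readings are left to the caller as
`t_level + t_level+1 + ...`. The post-wake capability `a<x>_t_<level>`
anchors at the offset of the **main** sleep — the clinical question is what
a subject can do after adequate rest — and is configurable to other
windows and levels; it is non-increasing in the level bound, non-decreasing
in the window length, and capped at the window length.

## The synthetic generator

`behavior_schedule()` tiles each analysis day with labelled segments, each
with a target epoch sigma. `simulate_recording()` renders a segment as a
fixed, randomly oriented unit gravity vector plus isotropic zero-mean
Gaussian noise on the three axes — the simplest model with a controllable
magnitude second moment, which is all the pipeline consumes. The per-axis
noise scale is calibrated so the standard deviation of the resulting
magnitude equals the target: for small targets the identity scale ≈ sigma
holds, but at vigorous levels (sigma ≈ 0.5 g against 1 g gravity) the
magnitude distribution is noticeably non-Gaussian, so the scale is solved
numerically from the closed-form 3-D Rician magnitude density (quadrature
mean plus `uniroot`), keeping the hour-averaged recovered sigma within
about 1% of target at every level. Optional quantisation reproduces a
12-bit ±8 g sensor (3.90625 mg steps, clipping with a warning).

`simulate_minute_ai()` is a minute-level shortcut (normal draws around the
segment mean `12 * sigma` with configurable relative jitter, truncated at
zero) for sleep-detection and regularity tests where the raw stage is not
under study. The generator's defaults — 20 Hz, 8-h night sleep at sigma
0.004 (minute AI ≈ 0.05), waking activity at AI ≥ 1, 20% relative jitter,
awakenings of 10–15 min — describe an ordinary adult routine as reported
in wear studies.

What the generator does **not** emulate: biomechanical wrist kinematics
(frequency content, axis correlations, hand-swing periodicity), non-wear
episodes, device calibration drift, and temperature or light channels.
Passing tests therefore demonstrate correctness of the computation chain
and recoverability of planted behavioural structure, not validity of the
thresholds on any particular clinical population.

## Problem sizes

The test suite and acceptance script run full-rate (20 Hz, 1.7 M samples)
simulations for single-day checks, drop to 2–4 Hz for multi-day pipeline
checks where only the composition is under test, use 50 seeded synthetic
days for the planted-sleep recovery rate, and 720-epoch (1-h) blocks per
target for sigma calibration. These sizes give Monte-Carlo error well
inside every asserted tolerance.

## Known limitations

* Thresholds (0.1/0.5/2.0/4.0 and the sleep constants) are fixed defaults
  derived from one device configuration at the wrist; other body sites,
  rates, or populations will need re-anchoring.
* The AI is orientation-free but not calibration-free: axis gain/offset
  errors propagate into sigma. Calibration is out of scope.
* The gravity-as-epoch-mean approximation degrades when orientation changes
  rapidly *within* an epoch; the resulting sigma inflation is part of the
  movement signal by construction.
* RI is a similarity score, not a significance test; no null distribution
  is attached.
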