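---
title: "Methods: prosthesis wear and free-living behaviour analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prosthesis wear and free-living behaviour analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbwear)
```

## The measurement problem

An upper-limb prosthesis user wears two monitors for about a week: a
tri-axial accelerometer at the prosthetic wrist and an activity monitor on
the thigh. The wrist stream answers *when is the prosthesis worn*; the
thigh stream answers *what is the person doing, and are they at home*.
limbwear turns these two streams into daily wear hours, donning/doffing
events, at-home versus away-from-home time, and stepping behaviour around
each don/doff event. All timestamps are timezone-naive local clock time
and every daily summary runs midnight to midnight.

## Activity-count emulation

Research-grade wrist accelerometers record raw g, but the non-wear
detection literature is calibrated on legacy "activity counts". The
package therefore reproduces the published count-emulation pipeline, per
axis and in this order:

1. linear-interpolation resample to 30 Hz;
2. band-pass IIR filter (21 published coefficients with a 0.965 gain;
   pass-band roughly 0.25–2.5 Hz, the frequency band of human movement);
3. decimate to 10 Hz;
4. saturate at ±2.13 g; rectify; zero values below the 0.068 g dead-band;
5. quantize at the 0.0164 g ADC step (`floor(v / 0.0164)`);
6. sum into minute epochs.

These constants live in `count_params()` as a versioned table; they are
the reference method's values, not tuning knobs. The per-epoch resultant
vector magnitude is the unrounded Euclidean norm of the three axis counts,
since downstream thresholds operate on it.

Two numerical choices are the package's own:

* **Steady-state filter initialisation.** The filter state is initialised
  as if the signal had been at its first sample value forever (past inputs
  `x[1]`, past outputs `x[1] · H(1)`). A recording that begins at rest then
  produces exactly its DC response — 0.044 g per 1 g of static input, well
  under the dead-band — instead of a start-up transient that would register
  spurious counts in the first epochs. With zero-state initialisation a
  recording beginning mid-gravity would look briefly "active".
* **Minute-anchored epoch grid.** Output epochs start at the first whole
  minute at or after the recording start and a trailing partial epoch is
  discarded, so epoch grids from different devices land on the same
  midnight-anchored grid without resampling.

## Non-wear detection

`detect_wear()` implements a parameterised run-length rule on epoch vector
magnitudes: a maximal run of epochs with `vm ≤ zero_threshold` (default 0
counts) lasting at least `min_nonwear_run` minutes (default 60) is
non-wear. Within a candidate run, up to `spike_tolerance_epochs` (default
2) isolated epochs with `vm ≤ spike_max_vm` (default 50 counts) are
absorbed — brief knocks to an otherwise stationary sensor. The semantics
are a union: an epoch is doffed if *any* qualifying interval covers it;
qualifying intervals start and end on still epochs and never contain two
adjacent spikes. The test suite checks this definition against a
brute-force oracle that enumerates every interval.

Because a prosthesis-mounted sensor cannot move when the prosthesis is in
a corner of the room, sensor non-wear is read as prosthesis non-wear; a
sensor embedded in the socket is treated identically. Donning events are
doffed→worn transitions (stamped at the first worn epoch), doffing events
worn→doffed. Transitions into or out of missing data produce no events, so
30-min behaviour windows are never attached to recording boundaries.

Daily wear hours are reported for every day; group summaries use only days
above a configurable observed-hours floor (default 20 h, the same rule the
thigh stream uses — the least surprising symmetric choice, exposed in
`daily_wear_summary()`).

## Home and community

A transition event is a stepping bout strictly longer than 60 s, or — when
a heading series is supplied — a bout with a sub-segment of at least 25 s
whose cumulative absolute heading change stays within
`straight_max_turn_deg` (default 30°; the straightness threshold is not
quantified in the source literature, so it is configuration and excluded
from acceptance checks). Minute epochs cannot represent exact continuity,
so bouts are reconstructed as maximal runs of epochs with at least 55 s of
stepping, the bout duration being the summed stepping seconds of the run.

Sleep periods are maximal runs of epochs dominated by primary lying,
merging interruptions up to 15 min, with a 3 h minimum — long enough to
exclude daytime naps, which by default do not act as anchors. Each day's
classification then runs a toggle state machine: at home after the night's
sleep; the first transition after sleep is leaving home; every subsequent
transition flips the state; the last transition before the next sleep is
returning home. The anchors alone (as described in the source method)
cannot represent multiple daily excursions, so the toggle model is the
minimal consistent extension; an `anchors_only` mode reports the
first-to-last-transition span instead, since either reading of "time away"
is defensible. With an odd transition count between anchors the final
unpaired transition closes at the returning anchor, contributing a
zero-length interval — i.e. it is ignored rather than allowed to leave the
day "open". Dominant-class ties are broken by a fixed priority (stepping >
cycling > upright > seated transport > sedentary > secondary lying >
primary lying > non-wear): ties are measure-zero in field data but tests
need determinism, and the rarer, more informative class wins.

`observed_hours` counts monitor-on-body time (present epochs minus their
non-wear seconds); "more than 20 h" is strict, so a 20.0 h day is invalid.
Missing epochs are preserved as missing by the readers — the valid-day
rule is about data collected, never about inactivity.

## Fusing the streams

`align_streams()` shifts the thigh table by a configured clock offset
(thigh minus wrist, seconds) and snaps it to the wrist epoch grid. The
offset is configuration because monitor clocks are assessed against each
other at programming time; `estimate_clock_offset()` cross-correlates
wrist vector magnitude with thigh steps and reports a lag, but the
estimate is advisory and never silently applied.

For each don/doff event, `stepping_around_events()` counts epochs with any
stepping (`stepping seconds > 0`; a dominant-stepping mode exists for
sensitivity analysis) in `[t − 30 min, t)` and `(t, t + 30 min]`. Windows
truncated by data boundaries, containing monitor non-wear, or overlapping
a neighbouring event are flagged incomplete and excluded from group means
— the conservative reading of a fixed 30-min window design; group-phase
cells with no events are reported missing, never zero.

## The synthetic cohort

`simulate_truth()` draws, per participant-day: a main nightly sleep
(22:00→06:30 ± 30 min SD); one or two away excursions of 1.5–4 h, each
*bounded by* a transition walk starting exactly at the departure and
return times; prosthesis wear tied to excursions (don 2–8 min before
departure, doff 5–25 min after return, with probability
`don_at_departure_prob`, default 1) plus at-home wear blocks topping daily
wear up towards a group-phase target; and short (15–50 s) stepping bouts
at home and away. Group-phase wear targets default to a pattern in which
previous users are stable near 11 h/day and new users rise from low early
wear to ~9 h/day months later — configuration that loosely imitates the
shape of published cohorts, not data.

Structural guarantees worth stating, because the recovery tests lean on
them:

* **Transition walks are 240–360 s.** A walk of duration D seconds keeps
  at least D − 110 s inside fully-stepping (≥ 55 s) epochs whatever its
  phase on the minute grid, so D ≥ 225 guarantees a reconstructed bout
  longer than 60 s — every excursion boundary is detectable. Non-boundary
  bouts stay under 55 s with starts at least 150 s apart, so they can
  never assemble a spurious transition.
* **Doffed gaps are at least 70 min** (above the 60-min non-wear run) and
  worn periods contain movement bursts at the don and doff boundaries and
  every 15 min in between, so intended non-wear is always detectable and
  worn time is never misread as non-wear. Bursts are 1–3 Hz (gait-band)
  oscillations of 0.5 g that survive the count band-pass; doffed-period
  sensor noise (SD 0.003 g) stays far below the dead-band, so doffed time
  emulates to exactly zero counts.
* **The recording runs 10 h past the last midnight** (`tail_hours`), as in
  field deployments where monitors are collected the morning after the
  final day — otherwise the last night's sleep would be truncated below
  the 3 h minimum and the final day would lose its returning-home anchor.
* The wrist renderer works at the signal level (50 Hz raw g), so the count
  emulation stage is exercised, never bypassed.

What the generator does **not** emulate: biomechanically realistic gait
accelerations (bursts are band-limited tones), orientation dynamics of a
swinging arm, magnetometer-informed posture classification errors in the
thigh stream (class seconds are rendered exactly from the schedule), naps,
shift-work sleep, or monitor faults. Passing recovery tests therefore show
the analysis logic is correct under the stated behavioural structure; they
do not certify classifier robustness to messy real signals.

## Problem sizes and runtime

The end-to-end recovery test and the acceptance script use the default
8-participant × 7-day cohort (about 242 million raw wrist samples,
rendered and emulated day by day to bound memory); the determinism and
example checks use 2 × 2 cohorts. On one CPU the full test suite runs in
roughly seven minutes and the acceptance script in about five.

## Known limitations

* Non-wear parameters default to the run-length rule above; studies tied
  to a specific published non-wear implementation should set
  `nonwear_params()` to that implementation's values.
* The toggle home/away model misreads qualifying walks that are not
  environment transitions (e.g. a long indoor corridor walk) as
  boundary crossings; the straight-line rule requires heading data that
  thigh monitors do not always provide.
* Counts are emulated, not device-native: firmware idiosyncrasies such as
  low-frequency-extension modes are out of scope.
* Steps in rendered thigh tables are rounded per epoch, so bout step
  totals conserve cadence × duration only to within ±0.5 step per epoch.
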