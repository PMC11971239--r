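# limbwear

Free-living analytics for upper-limb prosthesis users monitored with two
wearable sensors: a tri-axial accelerometer mounted at the prosthetic wrist
(recording whether and when the prosthesis is worn) and a thigh-worn
activity monitor (recording posture, stepping and sleep). The package is
aimed at rehabilitation and physical-behaviour researchers who want to
quantify, from a week of field recordings per participant, how much a
prosthesis is actually used at home, and how donning and doffing relate to
activity and to time spent away from home.

## What it computes

**Prosthesis wear.** Raw 50 Hz wrist acceleration is converted to legacy
per-epoch activity counts: per axis, resample to 30 Hz, band-pass filter
(~0.25–2.5 Hz, the published 21-coefficient IIR), decimate to 10 Hz,
saturate at 2.13 g, rectify, zero below the 0.068 g dead-band, quantize at
0.0164 g, and sum into 60-s epochs. The per-epoch resultant vector
magnitude `vm = sqrt(x² + y² + z²)` feeds a run-length non-wear detector:
a maximal run of `vm ≤ τ` epochs lasting at least 60 min is non-wear, with
up to 2 isolated low-magnitude "spike" epochs absorbed per run. Non-wear of
the wrist sensor is taken as non-wear of the prosthesis; state transitions
give donning and doffing events, and worn epochs give hours/day.

**Home and community.** Each 60-s thigh epoch carries seconds per activity
class (sedentary, upright, stepping, cycling, primary lying, secondary
lying, seated transport, non-wear) plus steps. A *transition event* is a
stepping bout continuously longer than 60 s (or, with heading data, more
than 25 s walked in a straight line) — behaviour unlikely inside a home.
Anchored on the main nightly sleep (primary lying), the first transition
after sleep marks leaving home, the last before sleep marks returning, and
transitions in between toggle the home/away state. Days with more than
20 h of monitor data count as valid; away hours are reported per
midnight-to-midnight day.

**Fusion.** Both streams are aligned on one epoch grid (with an explicit,
configurable clock offset) and stepping minutes are counted in the 30-min
windows before and after every don and doff event, then averaged per
participant group and monitoring phase.

**Synthetic cohorts.** A seeded generator produces ground-truth schedules
(sleep, excursions bounded by transition walks, wear intervals tied to
departures, stepping bouts) and renders them as raw wrist signal and thigh
epoch tables, so the full pipeline is testable end to end without any
field data.

## Worked example

```r
library(limbwear)

# counts from a synthetic 0.6 g gait-band oscillation, 5 minutes at 50 Hz
rec <- raw_triaxial(
  start_time = "2024-03-04 08:00:00", rate = 50,
  samples = cbind(0.6 * sin(2 * pi * 1.8 * (0:14999) / 50), 0, 1))
head(emulate_counts(rec), 3)
#>           epoch_start counts_x counts_y counts_z   vm
#> 1 2024-03-04 08:00:00     8090        0        0 8090
#> 2 2024-03-04 08:01:00     8112        0        0 8112
#> 3 2024-03-04 08:02:00     8112        0        0 8112

# a small synthetic cohort through the whole pipeline
cfg <- cohort_config(n_participants = 2, n_days = 2, seed = 421)
res <- run_cohort_pipeline(cfg)
subset(res$wear_daily, valid)
#>         date wear_hours observed_hours valid participant_id
#> 1 2024-03-04  10.266667             24  TRUE             P1
#> 2 2024-03-05   9.516667             24  TRUE             P1
#> 4 2024-03-04   6.633333             24  TRUE             P2
#> 5 2024-03-05   6.300000             24  TRUE             P2

res$group_summary[, -2]
#>           group kind mean_pre_stepping_min mean_post_stepping_min n_events
#> 1      new_user  don             0.5000000              6.0000000        4
#> 2 previous_user  don             0.6666667              3.8333333        6
#> 3      new_user doff             7.2500000              0.5000000        4
#> 4 previous_user doff             5.0000000              0.8333333        6
```

Participants step far more in the half hour after putting the prosthesis
on (and before taking it off) than after taking it off — the don-at-
departure structure the generator builds in. Comparing the estimates with
the generating truth:

```r
round(unlist(evaluate_recovery(res)[c(
  "wear_mae_h", "event_match_rate", "away_mae_h", "mean_jaccard",
  "mean_post_don", "mean_post_doff")]), 3)
#>       wear_mae_h event_match_rate       away_mae_h     mean_jaccard
#>            0.041            1.000            0.009            0.995
#>    mean_post_don   mean_post_doff
#>            4.700            0.700
```

Daily wear hours are recovered to a few minutes, all don/doff events are
matched, and classified away-from-home intervals overlap the true
excursions almost perfectly.

## Reading field data

`read_raw_wrist()` ingests timestamped CSV or the resampled 3-channel WAV
export dialect (per-unit g scale and channel order declared in a
`dialect()`), `read_behaviour_epochs()` ingests per-minute thigh CSV
exports with arbitrary column naming via the dialect's column map, and
`export_results()` writes deterministic CSVs plus a manifest with config
hash and input checksums. Deposited study datasets can be mapped onto the
pipeline by authoring a dialect for their file layout.
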