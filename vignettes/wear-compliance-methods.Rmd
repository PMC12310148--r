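---
title: "Wear-time compliance analysis: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wear-time compliance analysis: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearcomply)
```

## The problem

Consumer wrist wearables (Fitbit-class devices) are increasingly used to
measure physical activity and sleep in clinical cohorts — here, pediatric
pain patients in three settings: post-orthopedic surgery, post-cardiac
surgery, and an intensive interdisciplinary pain treatment (IIPT) day
program. Before such devices can carry outcome measures, a study must show
participants actually wear them. `wearcomply` implements the full
feasibility pipeline for that question: simulate realistic device streams,
ingest raw JSON exports, infer wear time, classify day and night compliance,
raise monitoring flags, and compute the group summary statistics.

## The wear-inference model

The device never reports "worn"; wear must be inferred from data presence.
The rule used throughout is:

> a minute is worn ⇔ it carries a heart-rate sample, or a step sample with
> value strictly greater than zero.

Two asymmetries are deliberate. First, *absence and zero are different
observations*: a worn sedentary minute records `steps = 0`, an unworn minute
records nothing at all, and the ingest layer preserves that distinction
(`NA` vs `0`). Second, a recorded zero is **not** wear evidence, because
devices register zero steps while sitting on a table. The cost of that
choice is visible in clip mode (below): a worn-but-sedentary minute with the
optical sensor off is indistinguishable from nonwear. On simulated data the
tests verify exactly this: without clip-mode artifacts the inferred mask
equals the generator's ground truth minute for minute; with clip mode,
disagreement is confined to worn-sedentary minutes.

## Compliance rules

* **Day rule** — a calendar day is compliant when worn minutes *outside any
  sleep period* total at least `day_threshold_min` (default 600, inclusive:
  exactly 600 is compliant). Sleep periods overlapping the date are
  subtracted minute-wise even when they belong to an adjacent night, which
  is the literal reading of "excluding sleep periods".
* **Night rule** — a night is compliant when the longest run of
  *consecutive* worn minutes inside its logged sleep period reaches
  `night_threshold_min` (default 180, inclusive). Total minutes do not
  matter: two 120-minute runs split by a 10-minute gap fail.
* **Trimming** — the first and last calendar days are excluded when partial
  (the grid does not span 00:00–23:59 local), and the first logged night is
  always excluded. A day is "partial" iff its epoch coverage misses either
  edge minute; this operationalizes the concept deterministically.
* **Nights without a sleep log contribute no study night.** The night rule
  is defined *within* a sleep period, so a missing log makes the night
  unassessable; counting it as noncompliant would conflate missing sleep
  detection with nonwear. Consequently day and night denominators differ,
  and the package reports the two rates separately rather than guessing a
  combined day-AND-night rule the source analysis never states.
* **Rounding** — compliance percentages are rounded half-up to two decimals
  (the printed `86.67` / `95.65` style), via `round_half_up()`, not base R's
  half-to-even.

Day boundaries use a fixed per-participant UTC offset; epochs are half-open
minute intervals `[t, t + 60 s)`. A sleep period is attributed to the night
labeled by its wake-up date, which gives one unambiguous night per period
even across midnight. A grid minute "belongs" to a sleep period when at
least 30 s of it lies inside the period — the same ≥1-of-2-subepochs rule
used to reconcile 30-second sleep stages with 1-minute activity epochs
(`resample_sleep_to_minutes()`); that reconciliation is a package decision,
since the source describes both resolutions but not the merge rule.

## The synthetic cohort

`sim_config()` states the world once; `generate_cohort()` realizes it. The
defaults emulate the motivating deployment:

| parameter | default | why |
|---|---|---|
| `n_per_group` | 9 / 22 / 27 | compliance completers per group |
| `study_days` | 20 acute, 24 chronic | ~3 weeks post-surgical wear; ~4-week IIPT admission |
| `wear_prob_day` | 0.82 / 0.75 / 0.90 | minute-level wear propensities chosen so day-compliance medians land near the high-80s (acute) / mid-90s (chronic) percent range; the source reports outcomes, not propensities |
| `wear_prob_night` | 0.92 / 0.90 / 0.95 | same reasoning for the within-sleep rule |
| `wear_mode` | `"bouts"` | wear/nonwear alternates in geometric bouts (mean cycle `bout_cycle_minutes` = 240), so the 180-continuous-minute rule is nontrivial; `"iid"` is available for analytic calibration |
| `mean_sleep_minutes` | 480 (SD 45) | age-typical sleep duration, onset ~23:00 |
| `charge_interval_days` / `charge_gap_minutes` | 7 / 120 | weekly charging, a known low-compliance window |
| `sync_interval_days` | 2–3 | the instructed sync cadence |
| `clip_mode_prob` | 0.01/day | rare but real: one participant lost two weeks of data this way |
| `storage_window_days` | 7 | on-device high-resolution retention |

Under `"bouts"`, the mean worn bout is `p · cycle` and the mean off-wrist
bout `(1 − p) · cycle`, making the stationary worn fraction exactly `p` —
so the same `wear_prob` parameter is comparable across both modes.
Acceptability item scores are drawn per group from Gaussian profiles whose
default means/SDs equal the published summary cells, clipped to the 0–10
scale and left continuous (rounding to integers would break the
`sd = 0 ⇒ all responses equal the mean` contract); the sleep-disturbance
item exists only for the chronic group. Adverse-reaction probabilities
default to 3/31 and 6/26.

Determinism: each participant's stream comes from a substream seeded by an
FNV-1a hash of `(master seed, group, index)`, so cohorts are reproducible
byte-for-byte at the raw-export level and independent of generation order.

What the generator does **not** emulate: physiological heart-rate waveform
structure, circadian modulation, the proprietary sleep-staging algorithm
(stages are sampled run-length encoded, not inferred), or calibrated
off-wrist bout lengths — no published bout-length distribution exists for
this cohort, so bout parameters are free configuration. A green simulation
test therefore establishes the *rules* are implemented correctly, not that
the simulated cohort is distributionally identical to the real one.

## Device artifacts

* **Clip mode** (`inject_clip_mode()`): the optical sensor is off — heart
  rate removed, sleep logs touching those days suppressed, steps retained.
* **Storage truncation** (`apply_storage_truncation()`): a minute sample is
  lost when the first sync at or after it comes more than
  `storage_window_days` later, or never comes. Daily summaries are computed
  before truncation and survive for every study day.

## Statistics

Group contrasts mirror the published analysis: pooled (Student) two-sample
*t* tests for the acceptability items — pooled rather than Welch because
the published df of `n₁ + n₂ − 2 = 29` for a 10-vs-21 comparison forces it
(Welch stays behind `welch = TRUE`) — and Mann-Whitney U for the compliance
counts and rates. The U statistic is the rank-sum form
`U = R₁ − n₁(n₁+1)/2` with midranks, reported for the first-listed group
(the complementary `U' = n₁n₂ − U` is attached, since the published
orientation is not determinable). The two-sided p is exact (null
distribution of U) for tie-free samples with `n₁·n₂ ≤ 400`, otherwise a
normal approximation with tie-corrected variance and *no* continuity
correction — a documented default that cannot be verified against the
source. No multiple-testing correction is applied, matching the uncorrected
reporting.

### Numerical notes

* Recomputing the published *t* statistics from the printed `(mean, SD, n)`
  cells reproduces −0.57 (comfort, orthopedic vs cardiac) and 1.39 (burden,
  acute vs chronic) at two decimals. The burden orthopedic-vs-cardiac cell
  prints 1.27 but recomputes to 1.2646 from the rounded cells — an
  input-rounding artifact of the same kind as the printed −0.71 that
  recomputes to −0.70. The tests freeze the recomputed value and assert the
  printed one is recovered to within one unit in the second decimal.
* Timestamps parsed through `strptime` can carry ~1e-11 s float error; the
  parser snaps instants to whole seconds before any grid arithmetic.
* Zero pooled variance with equal means yields `t = 0, p = 1`; with unequal
  means it is an error rather than an infinite statistic.

## Monitoring

The daily review loop flags a participant after `sync_lapse_days` (3) whole
days without a sync — counted from the most recent sync's calendar date,
which is day 0 — or `noncompliance_streak_days` (2) consecutive
noncompliant in-window days ("compliance issues" are day-rule failures;
which rule the source meant is unstated, so this is configurable). Each
streak produces exactly one flag, anchored at the day its threshold is
first met; flags clear when the condition ends and may re-raise. Reports
are plain text plus `flags.csv`; everything after the timestamp header is a
deterministic function of the inputs.

## Calibration checks the tests run

* With i.i.d. wear at `p = 0.6` and a fixed 440-minute sleep schedule the
  awake grid is exactly 1000 minutes/day, and the compliant-day fraction
  over 100 participants must match `P(Bin(1000, 0.6) ≥ 600)` within 3
  percentage points.
* A chronic group with strictly dominant wear propensity (0.92 vs 0.65)
  must win the Mann-Whitney day-rate comparison at p < .05 in ≥ 90 of 100
  seeded replicates. The replicate cohorts are deliberately small
  (4+4 acute vs 10 chronic over 8 study days) to keep the check inside its
  time budget; dominance at these effect sizes is so strong that power is
  effectively 1 regardless.
* The binomial-example scale-down: the adverse-reaction draw check uses 60
  seeds rather than 200, with the binomial 99% interval scaled to match.

## Known limitations

Sleep-log parsing accepts only the documented dialect, not the full public
API surface (no HRV, no TCX/GPX, no OAuth). Alternative non-wear algorithms
(Choi, Troiano) are out of scope beyond the pluggable mask function. The
partial-day test is strict: a single missing edge minute marks a day
partial. Medians use the midpoint convention throughout; if the original
analysis used a different quantile rule for even n, per-participant medians
could differ in the second decimal.
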