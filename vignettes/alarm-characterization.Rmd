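---
title: "Characterizing early-warning alarm performance by warning timeliness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing early-warning alarm performance by warning timeliness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmprofile)
```

## The problem

An early-warning index watches a continuously monitored patient and raises an
alarm when a scalar score crosses a threshold. Traditional evaluation treats
each monitored record as a single positive or negative and reports positive
predictive value (PPV), sensitivity, and false positive rate (FPR = 1 −
specificity). That framing discards two things that matter at the bedside:
*when* the warning came relative to the event, and *how many* warnings the
clinician had to field. Two systems with identical per-record PPV can differ
enormously in lead time and alarm burden.

`alarmprofile` characterizes a warning system by categorizing **every**
warning it raises. The fiducial points of a warning are the event time
$t_{\mathrm{EVENT}}$, the warning onset $t_{\mathrm{WARNING}}$, and the lead
time

$$T_{\mathrm{WARNING}} = t_{\mathrm{EVENT}} - t_{\mathrm{WARNING}}.$$

Two application-defined constants bound the actionable window:
$T_{\mathrm{MAX}}$, the longest lead at which a warning is still meaningful,
and $T_{\mathrm{MIN}}$, the shortest lead that leaves time to act
($T_{\mathrm{MIN}}$ may be zero or negative when acting at or after the event
is still useful). Each warning then falls into one of five bins:

| Bin | Rule |
|---|---|
| False | warning on a record with no event ($t_{\mathrm{EVENT}}$ undefined) |
| Early | event-record warning with $T_{\mathrm{WARNING}} \ge T_{\mathrm{MAX}}$ |
| On Time | $T_{\mathrm{MAX}} > T_{\mathrm{WARNING}} \ge T_{\mathrm{MIN}}$ |
| Late | $T_{\mathrm{WARNING}} < T_{\mathrm{MIN}}$ (including onsets after the event) |
| Missed | event record with no warning at all ($t_{\mathrm{WARNING}}$ undefined) |

Only the warning **onset** is binned: an episode that starts Early and stays
active into the actionable window is still Early. Both window boundaries are
inherited as written — closed below, open above — so a lead of exactly
$T_{\mathrm{MAX}}$ is Early and exactly $T_{\mathrm{MIN}}$ is On Time.

The tallies are normalized two ways:

* **Warning proportions** (unit of analysis: one warning). Every bin —
  including Missed, which counts unwarned event records rather than
  warnings — is divided by the total number of warnings
  (False + Early + On Time + Late). The four warning bins sum to exactly 1;
  the On Time bar estimates the probability that a warning heralds an event
  inside the actionable window, a per-warning analogue of PPV.
* **Warnings per record** (unit of analysis: one record). False is divided
  by the number of non-event records; the four event-side bins by the number
  of event records. Bars are unbounded above: an event-side sum exceeding 1
  exposes warning burden (multiple warnings per event).

Traditional per-record metrics are computed alongside for comparison: an
event record is a true positive when its warning state is active at *any*
sample whose lead falls inside the same half-open window, and a non-event
record with any active sample is a single false positive.

## The demonstration indicator: normalized Shock Index

The Shock Index is heart rate over systolic blood pressure, $SI =
\mathrm{HR}/\mathrm{SBP}$. To put it on a 0–1 scale, `fit_baseline_stats()`
pools the $SI$ samples inside each *event* record's baseline window —
non-event records are excluded, so the normalization is anchored to the
event population's resting physiology — and `normalize_si()` maps values
through the Gaussian CDF:

$$SI_{\mathrm{NORM}} = \Phi\!\left(\frac{SI - \hat\mu}{\hat\sigma}\right).$$

Two design choices here were genuinely open. The standard deviation is the
sample estimator ($n-1$ denominator), and pooling is across samples rather
than across per-record baseline means; both are the plain reading of
"population baseline mean and standard deviation" and are fixed, documented
conventions rather than tunable options. Numerically, $SI_{\mathrm{NORM}}$
is strictly inside $(0,1)$ but saturates to exactly 0 or 1 in double
precision beyond roughly $\pm 8\hat\sigma$; nothing downstream depends on
the open bounds.

## Alarm strategies

* **RESPONSIVE** (`responsive()`): the warning state is
  $SI_{\mathrm{NORM}} \ge$ threshold, sample by sample. The source material
  states the comparison both as $\ge 0.9$ and as "greater than 0.9"; the
  inclusive convention is adopted (it is stated first, and the boundary has
  measure zero on real data).
* **STAY-ON** (`stay_on()`): once on, the alarm holds until the indicator
  has been below threshold for a full off-delay (default 10 min). On the
  sampled grid the quiet time between two episodes is measured from the last
  active sample of one to the first active sample of the next; a gap shorter
  than the off-delay is filled entirely, merging the episodes. A literal
  automaton reading would instead fill the first `off_delay` minutes of
  *every* gap, but that operation is not idempotent (a partially filled long
  gap can shrink below the off-delay and merge on a second pass); the
  episode-merging reading is idempotent, and the two agree on warning onsets
  and episode counts — the only quantities the framework consumes. A record
  that ends inside a sub-off-delay quiet run keeps its latch on to the end:
  the turn-off condition was never met. Latched-episode offsets are read off
  the latched trace, so `extract_episodes()` always inverts exactly to the
  trace it was given.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `t_min` | 1 | min | shortest actionable lead |
| `t_max` | 14 | min | longest meaningful lead |
| `threshold` | 0.9 | — | warning when $SI_{\mathrm{NORM}} \ge$ threshold |
| `off_delay` | 10 | min | STAY-ON quiet time before release |
| `sample_interval` | 1 | min | uniform grid spacing |

The defaults are the case-study constants for a hemorrhage-induced
hypotension setting (the event is a ≥ 30 mmHg drop in mean arterial
pressure from baseline); for another application all five are free choices
that should come from subject-matter expertise.

## What the synthetic generator emulates — and what it does not

`generate_event_record()` emulates the monitored course of a controlled
hemorrhage: a stable baseline (default 30 min, matching the protocol's
"at least 30 min"), then linear drift — HR rising 1 beat/min, SBP falling
0.75 mmHg/min, MAP falling 1 mmHg/min — with independent Gaussian noise
per channel per sample. The event time is the first sample where MAP has
dropped 30 mmHg below the configured baseline mean, mirroring the
hemorrhage stopping criterion; with zero noise it lands exactly on the
closed-form crossing `baseline_duration + 30/map_drift`.
`generate_nonevent_record()` produces 2-hour stationary segments (the
control-record length chosen to approximate the longest event records).
Baseline variability (HR sd 5 beats/min, SBP sd 8 mmHg, MAP sd 4 mmHg) is
set to a physiologically plausible short-term spread; the non-event HR mean
(74 beats/min) sits low enough that control records flicker above the 0.9
threshold occasionally (a few false episodes per 2-h record) rather than
constantly.

What the generator does **not** model: baroreflex compensation, sepsis
dynamics, measurement artifacts, autocorrelated noise, or any coupling
between channels beyond the shared drift clock. Consequences worth knowing
when reading green tests: the per-sample independence of the noise makes
RESPONSIVE traces flicker more than real trend data, and the monotone drift
makes the first threshold crossing come early, so generated cohorts are
dominated by Early and False warnings (as the case study's RESPONSIVE
profile also was) and rarely produce Late or Missed rows; and over a full
2-h control record nearly every non-event record alarms at least once, so
the per-record FPR of generated cohorts runs higher than the case study's
5/12. A green pipeline test on generated data therefore establishes the
plumbing and the categorization arithmetic, not clinical realism.
`generate_fixture()` sidesteps the indicator entirely: it places
single-sample warning pulses at leads chosen inside each bin (snapped to
the sampling grid, two samples apart so pulses stay distinct episodes) and
is the tool of choice when a test needs exact bin counts.

## Numerical and reporting conventions

* **Rounding.** Displayed values are rounded with base R `round()` — IEC
  60559 round-half-to-even — to 2 decimals for profiles and 1 for percent
  metrics. This is deliberate: the case-study table prints 18/16 = 1.125 as
  1.12, 2/16 = 0.125 as 0.12 and 10/16 = 0.625 as 0.62, which
  half-away-from-zero rounding would not reproduce. Full precision is kept
  internally and in the CSV summaries.
* **Known discrepancy.** The case study prints a false positive rate of
  42.7% alongside the fraction 5/12, which is 41.7%; the package computes
  the fraction.
* **Degenerate inputs.** Zero warnings make warning proportions undefined:
  `warning_proportions()` errors, and the reporting layer flags the
  strategy instead of writing numbers. In `warnings_per_record()` a bin
  with zero records and zero warnings is reported as 0 and flagged; zero
  records with nonzero warnings is an error. A pooled baseline with zero
  variance is rejected rather than producing infinite z-scores.
* **Record-length disparity.** Profiles over records of very different
  lengths are misleading (longer records accumulate more warnings), so
  `build_fiducials()` warns — it does not error — when record spans differ
  by more than a factor of 2.

## A worked contrast

```{r case-study}
cfg <- framework_config()
resp <- profile_pair(bin_counts(n_false = 30, n_early = 18, n_on_time = 12,
                                n_late = 2, n_missed = 1,
                                n_event_records = 16,
                                n_nonevent_records = 12))
stay <- profile_pair(bin_counts(8, 6, 10, 1, 1, 16, 12))
round(rbind(responsive = resp$warning_proportions,
            stay_on = stay$warning_proportions), 2)
round(rbind(responsive = resp$warnings_per_record,
            stay_on = stay$warnings_per_record), 2)
```

The two strategies have identical traditional metrics on these data, yet
the profiles separate them sharply: RESPONSIVE spends 0.77 of its warning
mass on False + Early bins and carries an event-side burden of 2.06
warnings per event record, against 0.56 and 1.12 for STAY-ON — the latch
groups transient alerts without losing the timely ones.

## Limitations

* Multiple False warnings on one non-event record and single False warnings
  on several records are indistinguishable in the warnings-per-record
  profile (a limitation of the framework itself, inherited knowingly).
* One event per record; multi-event records are rejected at ingestion.
* No statistical test compares two strategies' profiles — the profiles are
  distributions, the traditional metrics point estimates, so only
  qualitative comparison is supported.
* Batch evaluation only; there is no streaming mode.
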