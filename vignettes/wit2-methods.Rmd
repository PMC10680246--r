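---
title: "Weight-based basal-bolus titration in silico: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-based basal-bolus titration in silico: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wit2sim)
```

## The problem this package addresses

Hospitalized patients with type 2 diabetes and marked hyperglycemia are
usually brought to target with a basal-bolus insulin regimen: a long-acting
analogue (glargine) once daily at bedtime and a rapid-acting analogue
(aspart) before each meal. The WIT2 algorithm removes the glucose-based
arithmetic from this process: both initiation and daily titration are fixed
per-kg-of-body-weight steps, so the whole regimen can be written on one
card. Two variants exist, distinguished by the basal:bolus ratio —
1:1.5 (total 0.5 U/kg/day: 0.2 basal + 3 × 0.1 bolus) and
1:1 (total 0.4 U/kg/day: 0.2 basal + 3 × 0.2/3 bolus).

`wit2sim` implements the dosing rules as a deterministic engine, adds the
accompanying standardized dietary prescription, and embeds both in an
in-silico two-arm trial with a synthetic virtual-patient cohort, so the
trial's design — endpoints, summaries, tests — can be exercised end to end
without any clinical data.

## The dosing engine

**Initiation** (day 1, the first day of insulin therapy): basal
0.2 U/kg at bedtime; the bolus total (0.3 or 0.2 U/kg by arm) divided into
three equal pre-meal parts.

**Daily titration** at the 09:00 round, one independent decision per
injection, governed by:

| injection | governing reading | target |
|---|---|---|
| basal | same-day fasting glucose (FBG) | < 7.8 mmol/L |
| breakfast bolus | same-day 2-h post-breakfast glucose | < 10.0 mmol/L |
| lunch bolus | previous-day 2-h post-lunch glucose | < 10.0 mmol/L |
| dinner bolus | previous-day 2-h post-dinner glucose | < 10.0 mmol/L |

If the governing reading is at or above target, the injection escalates by
its printed increment (basal +0.1 U/kg; meal bolus +0.05 U/kg in the 1:1.5
arm, +0.1/3 U/kg in the 1:1 arm); once the reading is below target the dose
holds. A hypoglycemic event (any reading < 3.9 mmol/L) in the preceding
24 h overrides everything for the injection it is attributed to and applies
the mirrored decrement.

Design choices where the protocol's prose left room:

* **Hypoglycemia action.** The algorithm table prints negative adjustments
  while the prose says titration "was held"; the table is treated as the
  normative statement (default `hypo_action = "reduce"`), with
  `hypo_action = "hold"` available.
* **Attribution.** Events are attributed to the temporally proximate
  injection by period of day (night 23:00–06:30 → basal; morning → breakfast
  bolus; afternoon → lunch bolus; evening → dinner bolus).
* **Suspension is not a lockout.** A meal bolus held at target resumes
  escalating if its reading later rises above target
  (`bolus_stop = "suspend"`; `"permanent"` is available). A permanent
  lockout is implausible in a treat-to-target protocol.
* **Timing of effect.** The 09:00 decision post-dates that morning's
  pre-breakfast injection: the breakfast delta therefore applies the next
  morning, lunch/dinner deltas the same day, and the basal delta at that
  night's injection. Day numbering: the basal injected at bedtime of day
  *d* first influences the FBG of day *d* + 1; titration decisions are
  issued from day 1 (on the admission-morning readings).
* **Threshold readings.** A reading exactly at 7.8 or 10.0 mmol/L counts as
  *above* target (the targets are "< 7.8" and "< 10.0").
* **Discretization.** The titration ledger is kept in exact U/kg; rounding
  to whole pen units (half away from zero) happens only at administration,
  so rounding never compounds across days.
* **Safety ceiling.** No maximum dose is part of the algorithm; a
  configurable guard (default 3.0 U/kg/day total) clamps runaway escalation
  in degenerate simulations and warns.

## The dietary prescription

Ideal body weight is height (cm) − 105. Total energy is 25 kcal/kg ideal
weight for overweight/obese patients and 30 for lean/normal (BMI cut-off
24 kg/m², configurable; the criterion for Chinese adults). Protein is
1.0 g/kg and fat 0.8 g/kg ideal weight; the remaining energy is
carbohydrate at 4/9/4 kcal/g Atwater factors; meals split 1:2:2. Note the
formula does not algebraically pin the carbohydrate share to 50–55 % — at
30 kcal/kg it computes ≈ 63 % — so the package reports the computed
`carb_fraction` rather than asserting a range.

## The virtual patient

The protocol only ever sees one reading per injection per day, so the
synthetic model is day-granular and first-order rather than a physiological
ODE. Patient *i* has untreated setpoints `fbg_base` and `ppg_base[meal]`
and responds to doses (all in U/kg) through linear setpoint depression:

* fasting setpoint: `fbg_base − s_basal · basal_prev_night`
* post-meal setpoint: `ppg_base[m] − s_bolus · bolus[m] − c_spill · basal_prev_night`

Latent levels move a fraction `lag` of the way to their setpoint each day;
readings add Gaussian noise (`noise_sd`) and are floored at 1.0 mmol/L; the
03:00 reading sits `nocturnal_dip` below the fasting latent. Hypoglycemia
is emergent — any realized reading below 3.9 mmol/L — not a separate event
process, and assisted (level 3) events are never generated.

Defaults (all overridable via `cohort_config()`):

| parameter | default | meaning |
|---|---|---|
| weight | 66 ± 11 kg, in [40, 120] | admission body weight |
| height | 164 ± 8 cm, in [145, 190] | for the dietary module |
| admission BG | 18.6 ± 5.4 mmol/L, in (10, 35] | inclusion requires > 10 |
| `fbg_base` | max(admission BG − 4.5, 8.2) | untreated fasting level |
| `ppg_base` | max(admission BG, 10.3) + (0.5, 1.0, 1.5) | untreated post-meal levels |
| `s_basal` | median 18, log-normal (sdlog 0.25) | mmol/L per U/kg basal |
| `s_bolus` | median 45, log-normal (sdlog 0.25) | mmol/L per U/kg bolus |
| `c_spill` | median 8, log-normal (sdlog 0.25) | basal carry-over on meals |
| `lag` | 0.75 ± 0.08 /day, in (0.3, 0.95] | daily approach fraction |
| `noise_sd` | 0.8 mmol/L | within-day variability (a modeling choice; no published estimate exists) |
| `nocturnal_dip` | 0.8 mmol/L | FBG-to-03:00 offset |

The sensitivity medians and `lag` were calibrated once on the noise-free
median patient so that both glycemic targets are reached in 3–4 days under
either arm (all four on day 3 in the 1:1.5 arm; FBG day 3, meals day 4 in
the 1:1 arm), the stated design point of the generator. A slower `lag`
with proportionally larger `s_basal` meets the same 3–4-day criterion but
makes glucose trail its setpoint by several titration steps, producing deep
overshoot and implausibly frequent nocturnal hypoglycemia; the chosen
kinetics keep the overshoot near one increment's worth.

Reproducibility: every random quantity descends from one integer seed.
Each patient id owns a deterministic substream (a stable 31-bit hash of the
id mixed with the seed), so profiles and simulated stays do not depend on
the order in which patients are generated.

**What the generator does not emulate:** meal-composition effects,
exercise, steroid therapy, renal/hepatic impairment, DKA physiology,
dropout, physician overrides, or any within-day dynamics. Passing
simulation tests therefore show that the *algorithm and trial machinery*
behave as specified under a plausible response model — they are not
evidence about clinical effect sizes, and the package deliberately does
not treat the trial's clinical outcome values as reproducible targets.

## The simulated trial

`run_trial()` samples one cohort, assigns arms 1:1 by a seeded random
permutation of the exact arm-label multiset, and runs each patient for up
to `max_days` (default 10, standing in for discharge), stopping early once
all four targets have been reached and a full day passes with no dose
change. Endpoints per patient: first-passage day per reading (FBG eligible
from day 2, since the first bedtime basal cannot act earlier; post-meal
readings from day 1, because the day-1 pre-meal bolus precedes them),
`NA`-censored if never reached; final administered doses in units/day; and
every hypoglycemic reading with its period and level.

`arm_report()` reproduces the results-section layout: mean ± SD
days-to-target (censored excluded and counted separately, as non-reachers
are reported as patient counts, not imputed days), mean ± SD final doses,
and per-period/per-level percentages of patients with hypoglycemia, each
with a cross-arm p-value — a summary-statistics Student t-test (pooled by
default, Welch available) for means and a 2×2 chi-square without
continuity correction for proportions (reported cells are ≥ 5; a
correction flag exists).

One subtlety the property tests document: escalating *faster* is monotone
per governed endpoint — raising the bolus increment never delays any
target, and raising the basal increment never delays the FBG target — but
an aggressive basal increment can transiently crash fasting glucose below
3.9 mmol/L, which the attribution rule charges to the breakfast bolus and
cuts it, occasionally delaying the post-breakfast target. That is a real
consequence of the algorithm's hypoglycemia rule, not a simulator artifact.

## Numerical and testing choices

* All dose ledgers are exact doubles; the only rounding site is
  `administered_units()` (half away from zero, matching pen practice).
* The 1:1 arm's per-meal quantities are kept as the exact binary double
  `0.1/3` rather than a decimal approximation.
* Noise-free runs are cross-checked against an independently coded scalar
  day-loop oracle over a 100-configuration sweep; stochastic checks use
  fixed seeds.
* Test problem sizes: cohort marginals at 4 × 10³ draws, trial-level
  checks at 89/93 patients per arm over 50 seeded replicates, property
  streams at 10³ random decision sequences — all sized to characterize the
  behaviour while keeping the default suite fast.

## Limitations

The virtual cohort is a modeling device: its response parameters are
calibrated to qualitative kinetics (days-to-target bands), not fitted to
patient data, so simulated hypoglycemia frequencies, dose distributions
and between-arm gaps should be read as structural behaviour of the
algorithm under the stated model, never as clinical estimates. The engine
implements exactly the two published arms; other ratios, correction
("sliding-scale supplement") doses, and mg/dL units are out of scope.
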