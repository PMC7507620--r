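---
title: "Methods: ensemble time-series modelling of AKI risk from ICU records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble time-series modelling of AKI risk from ICU records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the model
and its assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and
design choices made where the problem left them open. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from external results.

## Problem and data model

The prediction target is acute kidney injury (AKI) in ICU stays,
predicted 24 h or 48 h before onset from three long-format tables:
timestamped vital-sign/laboratory measurements, daily medication
administrations, and stay metadata. Time is modelled at calendar-day
resolution — records of this kind are organized by date, and all
downstream definitions (drug combinations, predictive points, KDIGO
windows) are daily. Internally days are integer offsets from admission
(day 0), so 24 h = 1 day and 48 h = 2 days. Demographics are
deliberately not used.

## Labelling: the binary KDIGO creatinine definition

A stay is AKI-positive if serum creatinine (mg/dl) rises by at least
0.3 mg/dl within 48 h or reaches at least 1.5 times baseline within
7 days; the onset day is the earliest day either criterion fires.
Two operationalizations had to be fixed:

- **Baseline** for the 1.5-fold rule is the first recorded creatinine
  of the stay — the most common retrospective convention.
- The **0.3 mg/dl rise** is tested against the minimum observed value in
  the preceding 2 days, the rolling-window reading of "within 48 hours".

Units are mg/dl only; μmol/l sources must be divided by 26.5 before
ingestion, which avoids silent unit mixing. Stays with an empty
creatinine series are unlabelable and are removed under the
insufficient-information rule together with stays carrying neither
measurements nor medications. The labeler is verified against an
exhaustive pair-scan oracle on 1000 random series per test run.

Only the binary creatinine definition is implemented: no urine-output
criteria and no stage 1/2/3 grading.

## Predictive points

Features are frozen at the *predictive point*: onset minus the lead for
positives. For negatives no convention exists in the KDIGO framing, so
the package anchors them at discharge minus the lead. This gives every
negative the maximal observation window and mirrors the positive
construction; it is a documented package choice, not a community
standard, and sensitivity to it has not been explored. Positives whose
onset falls within the lead of admission have no valid predictive point
and are filtered (counted with the short-stay rule).

## Feature generation

**Explicit indicators** are each variable's value at the admission day
and at the predictive point (two columns per variable). When several
measurements fall on one day the last value of the day is used — the
value a bedside system would report at day's end. Missing cells are
filled from the same patient's nearest-in-time observation, restricted
to days at or before the predictive point so nothing later than the
prediction time can leak in; distance ties prefer the earlier day
(information available sooner clinically). Patients lacking a variable
entirely receive the derivation-set median; medians are fitted on
derivation rows only and reused unchanged for validation. A column
empty in the whole derivation set falls back to 0 with a warning.

**Implicit indicators** encode medication history. The distinct drugs
given on one day form a *drug combination*; its canonical form is the
sorted vector of drug IDs and combination IDs are assigned in
lexicographic key order, so vocabularies are reproducible across runs,
platforms and row orders. A patient's sequence holds one combination
per medicated day up to and including the predictive point;
medication-free days contribute nothing. Weights are

IF(c, s) = f(c, s) / Σ f(·, s), ICF(c, P) = log(N / (1 + n_c)),
IFICF = IF · ICF,

with n_c counting *patients* (not days) whose sequence contains c.
Choices fixed here:

- **Log base**: natural. The base only rescales all implicit columns by
  one constant, which tree splits ignore.
- **Corpus scope**: the vocabulary, n_c and N are computed on
  derivation patients only and frozen for validation; validation-only
  combinations are treated as unseen (n_c = 0, no column of their own,
  but they still count in the IF denominator). Fitting on the full
  cohort would leak validation information into training.
- **N** counts all derivation samples, including patients with empty
  sequences (an empty sequence is still a sequence of the corpus).
- **Empty sequence**: an all-zero implicit row, not a division by zero.

The ablation encoders are `bool` (1 if the drug was ever given at or
before the predictive point), `times` (number of administration days)
and `none` (explicit block only). `bool` equals `times > 0` by
construction and by test.

## Classifier

Gradient-boosted trees (XGBoost) with 144 estimators, maximum depth 8
and minimum child weight 5 — hyperparameters typical for tabular
clinical data of this width; the learning rate is the backend default
(0.3). Training is single-threaded with a fixed seed so results are
bitwise reproducible. Any binary classifier exposing fit / score /
importance could be plugged behind `train_classifier()`, but the
boosted-tree backend is the default and the only one required.

## Imbalance handling

Three strategies operate on derivation indices only (one featurization
serves all): random undersampling of the majority class to a target
positive:negative ratio (rounded down; an unattainable ratio keeps
everything and warns rather than dropping minority samples), random
oversampling of the minority with replacement, and cost-sensitive
boosting with positive-class weight n_neg / n_pos. The ratio grid runs
10:1, 9:1, …, 1:1, …, 1:9, 1:10; note that enumeration contains 19
distinct points. The validation set is never resampled.

## Evaluation protocol

Per repeat: a stratified 60/40 split (class fractions preserved to
within one sample), vocabulary and medians fitted on the derivation
side, resampling applied, the model trained and scored on the untouched
validation side. Ten repeats by default; aggregates are means with
t-based 95% confidence half-widths (mean ± t₀.₉₇₅,₉ · sd/√10).
Metrics:

- **AUC** in the Mann–Whitney rank form with ascending mid-ranks for
  ties — equal to the probability a random positive outscores a random
  negative with half credit for ties, verified against a pairwise
  oracle.
- **Sensitivity** and **F1** at threshold 0.5 (configurable; 0.5 is the
  natural cut for a probabilistic classifier). F1 is 0 by convention
  when precision + sensitivity is 0.
- **Average precision** as the step-interpolated sum (no 11-point
  interpolation), with position-stable ordering under score ties.

Ablation variants run on identical split indices, so between-variant
comparisons use a *paired* two-sided t test on the per-repeat series; a
two-sample test would be wrong for shared splits and is not offered.
Zero-variance difference series cannot produce a t statistic and are
flagged degenerate (identical series report p = 1). Feature importance
uses XGBoost's gain measure (the least split-count-biased of the three
built-ins); implicit columns decode back to their drug-ID sets, and
top-k tables restricted to the implicit group mirror the
drug-combination importance read-out the model exists to provide.

## The synthetic cohort generator

The generator provides cohorts with the statistical structure the
pipeline assumes, so every stage is testable without restricted
clinical data. Per patient: stay length uniform on 3–14 days; daily
drug sets drawn without replacement from a geometric popularity law
(decay 0.65 over 25 drugs), so the head drug reaches most patients the
way one near-universal drug dominates real formularies; vitals are
AR(1) series (coefficient 0.7, innovation sd 0.5) around patient-level
offsets, with cells removed at the configured missingness rate (default
0.2); creatinine is recorded daily and never masked. The daily AKI
hazard is logistic: a base logit, a vitals term (0.8 × the first
vital's patient offset, giving the explicit block a genuine but bounded
signal), and any planted drug-combination effects, active once
cumulative exposure reaches the configured minimum days. The base logit
is calibrated by root-finding on the realized per-patient hazards so
the expected prevalence equals the target (default 0.15) — the
empirical prevalence then tracks the target to binomial accuracy.
Exposure to a planted combination is assigned independently of outcome
(a forced contiguous run of days on which the daily set is exactly the
combination, for 35% of patients, plus natural co-occurrence), so a
zero-effect plant produces no exposed/unexposed risk difference.

Creatinine is generated last, conditioned on the sampled event day:
event-free trajectories carry noise bounded inside both KDIGO criteria
(within-window rise ≤ 0.22 mg/dl, fold ratio ≤ 1.24), and the event day
forces a 0.35 mg/dl rise over the preceding 2-day minimum. Labels are
therefore true *by construction*, and `label_kdigo()` reproduces the
generator's intended label and onset day exactly on every patient — a
standing consistency test.

All draws descend from one root seed through per-patient substreams, so
per-patient output survives cohort reordering and regeneration is
byte-identical.

What the generator does **not** emulate: pharmacological realism
(drug–drug correlation beyond the plant, dosing, routes), hour-level
event times, informative missingness, measurement error in creatinine,
or the schema quirks of any real ICU database. Passing recovery tests
on these cohorts therefore demonstrates that the pipeline detects a
medication-combination signal of the planted form under realistic
sparsity and imbalance — not that it attains any particular performance
on real ICU data.

## Problem sizes and reproduction

The signal-recovery experiments use cohorts of 2000 stays at 15% target
prevalence with one planted two-drug combination at +2 logits — large
enough for stable paired comparisons over ten repeats while keeping a
full run in the order of a minute. Unit and property tests use cohorts
of 30–500 stays. `scripts/acceptance.R --seed S --out F` re-runs the
whole chain (generation, labelling, filtering, ablation, recovery,
ratio sweep) from scratch and writes the resulting numbers as JSON.

## Known limitations

- Day-level granularity cannot express sub-daily dynamics; a 23-hour
  creatinine rise spanning midnight counts as one day.
- The negative-class predictive point convention (discharge minus lead)
  couples feature windows to length of stay for negatives.
- The IFICF corpus statistics assume the derivation corpus is
  representative; small derivation sets make ICF noisy for rare
  combinations.
- The CLI `featurize` artifact fits vocabulary and medians on all
  samples it is given (it exists to build a final deployable model via
  `train`); protocol-grade evaluation always goes through
  `run_experiment()`/`ablate`, which refit per split.
- Only creatinine-based binary labelling is provided; cohorts labelled
  by urine output or staging need external labels.
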