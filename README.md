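# etsm

Early prediction of acute kidney injury (AKI) from longitudinal ICU
records, for clinical data scientists working with sparse, imbalanced
electronic-health-record tables. The package implements an ensemble
time-series model: daily medication history is turned into
drug-combination features weighted by a TF–IDF analogue, combined with
admission-day and predictive-point physiology, and classified with
gradient-boosted trees under a repeated stratified-split protocol. A
seeded synthetic ICU cohort generator with a plantable drug-combination
risk effect makes every stage testable without access to restricted
clinical databases.

## The model

**Labelling.** AKI is the binary KDIGO creatinine definition: serum
creatinine rising by ≥ 0.3 mg/dl within 48 h (against the minimum of the
preceding 2 days) or reaching ≥ 1.5× the stay baseline (first recorded
value) within 7 days. The onset day is the earliest day on which either
criterion fires. Stays without usable data, stays shorter than the
prediction lead, and AKI stays whose onset precedes any valid predictive
point are filtered out with full bookkeeping.

**Features.** Each prediction sample is a stay frozen at its *predictive
point* — 24 h or 48 h before onset for positives, the same lead before
discharge for negatives. Two indicator groups are built:

- *Explicit indicators*: each vital/lab variable at the admission day and
  at the predictive point. Missing values are filled from the patient's
  nearest visible observation (earlier day on ties), falling back to the
  derivation-set median.
- *Implicit indicators*: the set of distinct drugs given on one day is a
  *drug combination* c; over the derivation corpus P of per-patient
  day-ordered combination sequences s, each combination is weighted per
  patient by

      IFICF(c, s) = IF(c, s) · ICF(c, P)
      IF(c, s)  = f_{c,s} / Σ_{c'} f_{c',s}
      ICF(c, P) = log( N / (1 + n_c) )

  with f_{c,s} the number of days sequence s spent on combination c, N
  the number of derivation patients and n_c the number of sequences
  containing c. Ablation encoders replace the IFICF block by per-drug
  booleans (`bool`), per-drug day counts (`times`), or nothing (`none`).

**Classifier and protocol.** Gradient-boosted trees (XGBoost; 144
estimators, max depth 8, min child weight 5) trained on a 60 %
stratified derivation split — undersampled, oversampled or
cost-weighted to handle class imbalance — and scored on the untouched
40 % validation split; ten repeats. Metrics are the Mann–Whitney
rank-form AUC (mid-rank ties), sensitivity and F1 at threshold 0.5, and
step-summed average precision, with t-based 95 % confidence intervals
and paired t tests between feature variants on shared splits.

## Worked example

```r
library(etsm)

gen    <- generate_cohort(cohort_config(n_patients = 500, seed = 42))
labels <- label_kdigo(gen$cohort)
flt    <- filter_cohort(gen$cohort, labels, lead_hours = 24)
flt$report
#> <cohort_filter_report> lead 24 h: 500 stays; removed 0 (insufficient
#> information) + 0 (stay shorter than lead / no valid predictive point);
#> retained 500

report <- run_experiment(flt$cohort, flt$labels, lead_hours = 24,
                         encoder = "ificf", n_repeats = 10, seed = 42)
report
#> <metrics_report> encoder "ificf", lead 24 h, 10 repeats on 500 samples
#>   auc         0.593 ±0.029
#>   sensitivity 0.575 ±0.052
#>   f1          0.297 ±0.019
#>   ap          0.236 ±0.030

top <- report$top_combinations[[1]]
head(top[top$importance > 0, c("rank", "drug_ids", "importance")], 4)
#>   rank    drug_ids  importance
#> 1    1     D04,D06 0.099066421
#> 2    2         D01 0.062207954
#> 3    3 D01,D02,D03 0.034004388
#> 4    4     D01,D02 0.006151389
```

The summary lines are validation-set means ± 95 % CI half-widths over
the ten repeats. The default synthetic cohort plants a two-drug
combination (`D04`+`D06`, +2 logits of daily AKI hazard after two
exposure days); it surfaces as the top-ranked implicit feature, which is
exactly the feature-importance read-out the model is designed to give a
clinician. At n = 500 the AUC is modest; the planted signal separates
clearly at larger cohort sizes (see the reproduction script below).

A command-line pipeline (`simulate`, `label`, `featurize`, `train`,
`evaluate`, `ablate`, `sweep`) is exposed through `etsm_cli()` and the
thin wrapper `inst/cli/etsm`:

```sh
Rscript inst/cli/etsm simulate --config run.json --out artifacts
Rscript inst/cli/etsm label    --config run.json --out artifacts
Rscript inst/cli/etsm evaluate --config run.json --out artifacts
```

Every stage writes a provenance JSON (resolved config, seed, versions,
input digests); fixed-seed runs are byte-identical.

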