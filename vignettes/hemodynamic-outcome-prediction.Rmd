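---
title: "Predicting postoperative outcomes from intraoperative hemodynamics: methods"
author: "hemopred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postoperative outcomes from intraoperative hemodynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopred)
```

`hemopred` turns archived intraoperative monitoring records into binary
outcome predictions through four stages: waveform feature extraction,
label-blind subset selection, an exhaustive search over small
logistic-regression classifiers under leave-one-out cross-validation
(LOOCV), and ROC-based inference. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The data model

A cohort is a set of patient records, each carrying

* 15 **preoperative** features (demographics, comorbidities coded 0/1,
  ASA class 1–4, and laboratory values: INR, bilirubins, albumin,
  creatinine, MELD, BMI, age);
* 5 **non-hemodynamic intraoperative** features: volumes of whole blood,
  fresh frozen plasma, platelets and autotransfused red cells (mL/kg,
  `volume_per_kg()` helps when raw mL are recorded) and surgery duration
  (min);
* per-signal **hemodynamic waveforms**: time-stamped series (seconds from
  surgery start, strictly increasing) for up to 16 monitored variables.

Ten signals are recorded continuously (SBP, CVP, HR, SpO2, dPmx, PCCI,
PPV, SVI, SVRI, SVV); six indices are computed only intermittently (CFI,
ELWI, GEDI, GEF, ITBI, PVPI). Missing values stay `NA` — nothing is
imputed; `apply_inclusion_filters()` instead drops incomplete records and
logs the first failing reason per record.

## Waveform features

Each signal contributes up to three features (56 matrix columns in all):

* **median** — central tendency; the only feature for intermittent
  signals, whose sparse sampling makes variability and exposure measures
  unreliable;
* **MAD**, `median(|x - median(x)|)` — robust within-surgery variability.
  The 1.4826 normal-consistency factor is deliberately omitted: the
  feature is a descriptive variability measure, not a variance estimate;
* **exposure area** — the time integral of the excursion beyond the
  signal's "normal" threshold on its harmful side (`hd_signals()` lists
  all thresholds), in signal-unit·minutes. This captures *cumulative*
  exposure to a putatively dangerous condition: level and duration both
  matter.

Integration uses per-sample rectangles: monitors emit step-held values, so
each sample is held until the next one. Two numerical choices matter:

* **gap capping** (`max_gap_s`, default 60 s): a sample is held for at
  most the cap, so recording dropouts neither accrue area nor count as
  covered time. The same rule defines the coverage used by the 180-minute
  inclusion criterion (`signal_coverage_minutes()`), keeping the two
  consistent;
* the **final sample** is held for the series' median inter-sample
  interval (capped), so a constant series at level c yields exactly
  |c − τ| × covered-minutes — the rectangle identity asserted in the test
  suite. A trapezoidal rule is available via `rule = "trapezoid"` for
  signals better viewed as piecewise linear.

One threshold is genuinely ambiguous in the source material: the SVI
exposure direction. The package defaults to *below* 40 mL/m² — exposure
to reduced stroke volume, the clinically coherent reading — and exposes
`svi_direction` for the alternative.

## Label-blind subset selection

With dozens of correlated features and few outcome events,
multicollinearity destabilizes logistic-regression estimates. Before any
label is used, `select_feature_subset()`:

1. standardizes each column to (x − μ)/μ (`standardize_features()`), a
   mean-ratio scaling that makes features dimensionless relative to their
   cohort-average level. It is undefined for zero-mean columns; such
   columns raise an error pointing at the z-score alternative
   (`method = "zscore"`), which remains available but is not the default
   because the mean-ratio form is the package's canonical scaling;
2. orders columns by column-pivoted Householder QR (LAPACK `dgeqp3`):
   greedy pivoting picks, at each step, the column with the largest
   residual norm, so |diag(R)| is non-increasing and the leading k
   columns are the greedily most linearly independent k-subset. Pivoting
   is a heuristic — the tests check it lands within a factor of two of
   the exhaustively best-conditioned subset on small problems — but it is
   deterministic and label-blind by construction (the interface takes no
   labels);
3. keeps the largest prefix whose 2-norm condition number σ_max/σ_min is
   at most `cond_cap` (default 15, inside the commonly recommended 10–20
   band for regression design matrices). Prefix condition numbers need
   not be monotone in k, so the scan runs from the full width downward
   and takes the first satisfying k — the literal "largest number of
   features". If nothing satisfies the cap a single feature is kept, with
   a warning.

Selection runs once on *all* feature-complete records, with or without
outcome labels, so both outcomes share the same subsets.

## Exhaustive classifier search

`run_task()` enumerates every nonempty combination of at most
`max_features = 5` selected features (the cap limits the
feature-to-event ratio; `combination_count()` gives the totals, e.g.
1,023 for a pool of 11). The intercept is always included and never
counted against the cap; the intercept-only model is excluded by default
(`include_empty = TRUE` counts it).

Each combination gets a **full-data fit** — supplying multivariate odds
ratios exp(β) with 95% Wald intervals and P-values, in original feature
units (fitting raw values, not the standardized matrix, is what makes
"per mmHg·min" odds ratios possible) — and an **LOOCV score vector**:
each patient's predicted probability from a model trained on the other
n − 1 records. Because selection was global and label-blind, performing
it outside the CV loop leaks no label information.

The fitter is a dedicated Newton/IRLS routine (convergence when the
relative log-likelihood change falls below 1e-8, at most 100 iterations,
with step-halving): the search needs warm starts across folds (the
full-data coefficients start each fold, which cannot change the optimum
of the strictly concave fold likelihood but cuts iterations roughly in
half), a deterministic fallback, and fit counting (`fit_count()`; a task
costs exactly combinations × (n + 1) fits). On non-convergence, a
singular system, or any |coefficient| above 15 — the pragmatic
separation signal — the model is refit with an L2 penalty of
`ridge_lambda = 1e-6` on non-intercept coefficients and flagged
`ridge_fallback`. `stats::glm` and a BFGS optimizer on the penalized
likelihood serve as independent oracles in the test suite.

Results are ranked by AUC, ties broken by fewer features then
lexicographic names. Combinations are independent, so any execution order
yields identical results.

## Evaluation

* **AUC** (`roc_auc()`) is the Mann-Whitney statistic — concordant
  (case, control) pairs plus half the ties — identical to sweeping all
  distinct score thresholds, with no binning.
* **BCa intervals** (`bca_ci()`, default 1,000 replicates) resample the
  *fixed* per-patient LOOCV scores at the patient level. Re-running the
  whole LOOCV pipeline inside each replicate would cost three orders of
  magnitude more and is the less common convention for AUC intervals; the
  score-resampling default therefore carries a documented optimism caveat
  — it ignores training variability. Replicates that lose one class are
  redrawn and counted. Bias correction z₀ comes from the bootstrap
  fraction below the point estimate, acceleration a from jackknife
  skewness; with z₀ = a = 0 the endpoints reduce exactly to percentile
  endpoints (asserted in the tests). Intervals that fail to bracket the
  point estimate in degenerate resampling situations are flagged, not
  hidden.
* **DeLong comparisons** (`delong_test()`, `compare_task_reports()`) use
  the placement-value covariance structure for paired ROC curves;
  identical score vectors return P = 1 with a degeneracy flag.
* **Inclusion frequency** (`inclusion_frequency()`) counts, per feature,
  classifiers with AUC > 0.7 including it at Wald P < 0.05, split by
  odds-ratio direction. The 0.7 default reflects the approximate ceiling
  of preoperative-score-based mortality prediction in this surgical
  setting; a feature whose inclusions all fall on one side of OR = 1 is
  associated with risk in a single, stable direction.

A property worth knowing when reading null results: with labels
independent of all features, pooled LOOCV scores are *anti*-correlated
with the held-out label (leaving a case out lowers the training
prevalence), so the mean cross-validated AUC over many null classifiers
sits visibly **below** 0.5 at small n, while apparent (training) AUCs sit
above it and the best-of-many cross-validated AUC is pulled back toward
chance by selection. The test suite asserts exactly this behaviour rather
than a naive mean of 0.5.

## The synthetic cohort generator

`simulate_cohort()` produces cohorts with the statistical structure the
pipeline assumes, plus stored ground truth for recovery tests:

* **waveforms**: stationary AR(1) fluctuations around patient-specific
  baselines, sampled every 10 s, clipped to physiological ranges; lag-1
  correlation defaults to 0.97 at 10 s (a fluctuation timescale of
  minutes), so threshold crossings are sustained episodes — white noise
  would make median, MAD and exposure area near-degenerate functions of
  one another. Intermittent indices are emitted every 30 min;
* **preoperative labs** from a Gaussian copula (MELD positively
  correlated with INR, bilirubins, creatinine; negatively with albumin)
  with log-normal/normal margins centred on cohort-plausible medians, so
  subset selection faces realistic multicollinearity;
* **volumes and durations**: gamma-distributed mL/kg volumes; normal
  durations (mean 420, SD 90 min) truncated at 240 min;
* **outcomes**: Bernoulli draws from logit⁻¹(β₀ + Σ βx) on configured
  features, at target prevalences of 0.18 (mortality) and 0.21 (renal
  failure) by default. β₀ is root-found so the *expected* prevalence —
  the mean of logit⁻¹(β₀ + Σ βx) over the realized cohort — hits the
  target exactly; tuning on the realized cohort rather than a huge pilot
  draw avoids simulating hundreds of thousands of waveform-hours for a
  constant, at the cost of the intercept varying slightly between
  cohorts;
* **missingness** (`inject_missingness()`): completely-at-random deletion
  of preoperative cells, blood-product volumes or outcome labels, and
  truncation of waveforms below the 180-minute threshold.

The generator's defaults are chosen for test utility and are explicitly
non-clinical: it does not model surgical phases (anhepatic, reperfusion),
artifacts, informative missingness, or mechanistic coupling between
signals (each signal's fluctuation is independent given the baselines).
Passing recovery tests therefore demonstrates that the *pipeline* is
correct and unbiased under its own assumptions — not that those
assumptions hold in any clinical dataset.

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` validate at sizes chosen to
exercise every code path while keeping a single-CPU run in minutes: AUC
fuzzing on 1,000 cohorts of n ≤ 12 against brute-force pair counting; the
QR contract on 1,000 random matrices (25–40 × 3–9, half with a duplicated
column); whole-pipeline recovery on one 600-patient cohort with two
simulated channels (CVP, SVI — an 11-feature intraoperative pool) and a
two-feature true mortality model, asserting that the best classifier is
built on exactly the generating features and that its cross-validated AUC
lands within 0.05 of the generating model's AUC; DeLong size (1,000 null
replicates, n = 100 with 30 cases) and BCa coverage (500 replicates,
binormal scores with true AUC 0.75, 1,000 bootstrap draws each).

## Limitations

* The exhaustive search is O(combinations × n) logistic fits; pools much
  beyond ~30 features at the 5-feature cap become expensive in plain R.
* BCa intervals on score vectors inherit the optimism caveat above.
* The best-of-many AUC is a selected maximum; its confidence interval
  does not account for selection across combinations.
* Mean-ratio standardization presumes features with nonzero, meaningful
  means (true of this feature set; the z-score option covers the rest).
* The generator's realism limits are listed above; in particular it
  cannot validate robustness to artifacts or informative dropout.
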