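---
title: "Sparse proteomic risk signatures: models, assumptions and design choices"
author: "proteoRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse proteomic risk signatures: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

proteoRisk implements a three-stage framework for discovering and
evaluating sparse plasma-protein signatures that predict 10-year disease
incidence on top of basic clinical information:

1. **Feature selection.** L1-penalized fits over repeated subsamples of a
   dedicated selection split, with smoothed-bootstrap class rebalancing,
   aggregated into per-assay selection scores.
2. **Model optimization.** Penalized Cox proportional-hazards models
   (clinical benchmark; clinical + top-20/10/5 proteins; top-5 proteins
   alone), tuned by cross-validated partial-likelihood deviance.
3. **Validation.** Harrell's C-index over paired bootstrap resamples of a
   held-out validation split, screening metrics (detection rate,
   false-positive rate, likelihood ratio), category-free net
   reclassification and integrated discrimination improvement.

Because the cohorts that motivate this design are access-restricted, the
package ships a synthetic-cohort generator with known sparse signal
structure so every stage is testable end to end against ground truth.

## The synthetic cohort

`simulateCohort()` draws a samples-by-assays matrix of NPX-like (log2
relative abundance) values from block-equicorrelated Gaussians nested in
panels. Equicorrelated blocks are a deliberately adversarial choice for an
L1 selector: correlated neighbours of a causal assay compete for its
coefficient, which is exactly the behaviour a stability-style score has to
survive. Clinical covariates (age, sex, BMI, ethnicity, smoking, alcohol, a
family-history flag) get middle-aged population-cohort marginals; the family-history flag
is generated as an informative but non-causal proxy, correlated with the
true linear predictor on the log-odds scale.

Event times follow a proportional-hazards law with hazard
`baseline_rate * exp(lp)`, exponential by default (a Weibull shape is
available), with administrative censoring at the analysis horizon
(10 years by default) and optional exponential dropout. When a target case
count is requested, the baseline rate is calibrated by bisection on the
closed-form expected case count, to within 1% of the target. The default
configuration — 4,000 participants, 600 assays in four panels of 10-assay
blocks with rho = 0.3, five causal assays with log hazard ratios 0.5–1.5,
clinical log hazard ratios of 0.35/0.25/0.15/0.30 per standardized unit,
and ~400 expected cases over 10 years — is the regime all package-level
simulation checks run in: a rare-ish disease with a case count comfortably
above the 80-case inclusion floor. Smaller problem sizes used by
individual checks (for example 1,500 × 120 null cohorts, or 150 × 24
imputation cohorts) are stated where they are used; they were chosen once
as the smallest sizes at which the corresponding property is
well-identified.

What the generator deliberately does **not** emulate: assay-specific limit
of detection, plate effects beyond block missingness, non-proportional
hazards, informative censoring, and real NPX covariance (which is
unpublished). Passing tests therefore demonstrate internal correctness and
statistical calibration of the machinery, not performance on any real
cohort.

Cohort-inclusion rules mirror common epidemiological practice:
`applyIncidenceFilters()` removes prevalent cases and incident cases
recorded within the first 6 months of follow-up, and `makeSplits()`
refuses cohorts with fewer than 80 incident cases.

## Quality control and imputation

`flagSampleOutliers()` flags samples whose standardized first or second
principal-component score, per-sample median NPX, or per-sample IQR of NPX
lies more than 5 s.d. from the cohort mean. The PCA is computed jointly
over all assays on standardized, mean-filled values; whether the original
procedure ran per panel is not documented, so the joint variant was chosen
and is noted here as a design decision.

`imputeProteins()` is a missForest-style iterative imputer: assays are
visited in order of ascending missingness; each assay's missing cells are
predicted by a random forest (50 trees, grown on subsamples drawn without
replacement, `mtry` at its default of the square root of the predictor
count) fit on the other assays of the same panel plus age and sex. The
loop stops the first time the relative sum of squared changes in the
imputed values increases — the classic missForest criterion, chosen
because the algorithm family is named but the stopping variant is not —
and returns the last iterate before degradation. Observed cells are never
modified; samples missing more than 50% of their values are rejected
rather than imputed.

## Feature selection

The selection stage runs `n_iterations` (200 by default) independent
iterations. Each iteration:

1. draws 80% of the selection split without replacement (the subsample
   fraction is not pinned down by the framework description; 80% is the
   package's choice),
2. rebalances cases and controls with `smoothedBootstrapRebalance()`, a
   smoothed bootstrap that draws each synthetic row from a class-
   conditional Gaussian kernel centred on an observed row, with
   per-feature bandwidth `h_j = shrink * sd_j,class *
   (4/((d+2) n_class))^(1/(d+4))` (the multivariate Silverman rule),
3. standardizes the rebalanced subsample,
4. tunes the L1 penalty of a logistic model for the incident-within-
   horizon label over 50 log-spaced values from the data-derived
   `lambda_max` down to `1e-3 * lambda_max`, by 5-fold cross-validated
   deviance over 3 repeats, and
5. adds `|beta|` at the optimal penalty to each assay's selection score.

The choice of a *logistic* selection model deserves a note: rebalancing is
defined for class labels and is ill-posed for censored event times, so the
binary incident-within-horizon label is used at this stage, with
early-censored non-events excluded from the label; the Cox family is
available behind `family = "cox"` (without rebalancing) for comparison.
Under pure administrative censoring the exclusion is empty.

Numerical choices: coordinate-descent convergence for the selection-stage
fits uses a tolerance of `1e-4` rather than glmnet's default `1e-7`; the
selection score aggregates hundreds of fits, and at this tolerance the
per-fit coefficients agree with tightly converged ones to ~3e-3 with
identical supports, while the stage runs about four times faster. The
optimization-stage Cox fits keep the default tolerance.

Scores feed `rankTopK()` (descending score, lexicographic tie-break) and,
after the top-20 model is fitted, `sparsifyByWeightProduct()` ranks
penalized features by `|optimized weight| x selection score` to extract
the top-10 and top-5 signatures. Clinical covariates are never ranked:
they are retained in every augmented model.

## Risk models

`fitPenalizedCox()` maximizes the Cox partial likelihood minus an L1
penalty on the flagged features, over a 50-value log-spaced grid tuned by
5-fold cross-validated partial-likelihood deviance. Clinical covariates
are unpenalized in augmented models so that protein penalties cannot
displace the benchmark; whether the original models penalized them is not
stated, and this choice makes the benchmark comparison conservative. Ties
use the Breslow approximation, which also gives the closed-form Breslow
cumulative baseline hazard stored with each model; absolute risk at the
horizon is `1 - exp(-H0 * exp(x'beta))`. When nothing is penalized (or the
grid is exactly 0) the fit is an unpenalized Cox model. Categorical
covariates are one-hot encoded against a first-level reference.

`fitModelSuite()` fits the benchmark and augmented members on the
optimization split (the combined 70% set under the two-way rule), computes
validation C-indices, and records the best-performing protein signature
(highest validation C among the 5/10/20 variants) — the retention rule
used for all downstream comparisons. Models serialize to JSON at full
double precision (`%.17g`), so a reloaded model reproduces predictions
bit for bit; this is the transfer mechanism for frozen-weight evaluation
on an external cohort.

## Evaluation

`harrellC()` counts concordant pairs among comparable pairs (the earlier
time must be an event; equal event times are not comparable; tied scores
count 1/2), in compiled code, and is verified in the test suite against an
exhaustive O(n^2) enumeration oracle. `bootstrapCompare()` applies *the
same* bootstrap resample indices to both models — without pairing, the
difference distribution would confound model difference with resample
noise — and declares an improvement significant when the empirical
2.5–97.5 percentile interval of the per-replicate differences excludes
zero. Replicates without events are redrawn.

`screeningCurve()` sets, for each target FPR from 5% to 40%, the
positivity threshold at the corresponding upper quantile of the *control*
scores, so the realized FPR matches the target up to discreteness, and
tabulates TP/FP/TN/FN, DR = TP/(TP+FN), FPR = FP/(FP+TN) and LR = DR/FPR
(an exact identity on the counts). Case/control status at the horizon is:
case = incident event within the horizon; control = event-free with
follow-up reaching the horizon. Early-censored non-events are excluded
from these binary metrics — the conservative reading of an undocumented
rule; `controls = "all_noncases"` switches to the permissive one. The same
status rule drives `categoryFreeNRI()` (default margin 0.15 on the
absolute-risk scale, the conservative cut-off) and `idi()`. Both are plain
(non-IPCW) estimators, adequate under the generator's administrative
censoring; censoring-weighted variants are an explicit extension point.
`postTestProbability()` converts an LR and a pre-test probability through
odds.

`stratifiedEval()` repeats the paired comparison within strata (sex, age
of onset), skipping strata with fewer than 20 incident cases, and
`downsampleCases()` supports the sensitivity analysis that checks
improvements are not inflated as case counts shrink. Evaluating a 10-year
model at a 5-year horizon requires only changing the `horizon_years`
argument of the metric functions.

## Enrichment and reporting

`fisherEnrichment()` performs a two-sided Fisher exact test per annotation
label (tissue class, pathway, panel) on the selected-by-labelled 2x2 table
over a user-supplied background, reporting the sample odds ratio `ad/bc`
(Haldane 0.5 correction when a cell is empty — the zero-cell convention is
the package's choice) and Benjamini–Hochberg q-values via `bhAdjust()`.
Annotations are supplied as two-column tables; no online resources are
queried. `predictorSharingSummary()` tallies, across per-disease
signatures, how many diseases and clinical specialties select each assay,
its mean within-disease-normalized weight, and flags disease-specific
predictors (selected for exactly one disease with normalized weight
above 0.6).

## Interfaces

The package's surface is its exported R functions plus plain-text
interchange formats: cohorts as TSV/CSV (`writeCohort()`/`readCohort()`,
empty cell = missing), selection scores and screening curves as TSV, risk
models and simulation truth as JSON. These functions are the scriptable
equivalent of a subcommand-style command line; composing them in an
Rscript is a one-liner per stage.

## Known limitations

* The selection-stage label discards time-to-event resolution; with heavy
  non-administrative censoring the binary label loses information and the
  Cox selection variant may be preferable.
* cNRI and IDI are unweighted; under informative censoring they are
  biased.
* The generator's Gaussian, block-equicorrelated proteome is a stress
  model, not a portrait of real NPX covariance.
* Between-stratum comparisons use independent (unpaired) bootstrap
  distributions, since strata share no samples.
* The worked examples and calibration checks run at desk scale (thousands
  of samples, hundreds of assays); the algorithms are O(n p) per penalized
  fit and scale to biobank-sized inputs, but no parallel scheduler is
  built in — iterations are independently seeded precisely so one can be
  layered on.
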