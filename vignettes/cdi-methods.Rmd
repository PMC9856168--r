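---
title: "The Consciousness Domain Index: model, estimation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Consciousness Domain Index: model, estimation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

After severe acquired brain injury, patients may persist in a prolonged
disorder of consciousness (pDoC) — vegetative state / unresponsive
wakefulness syndrome (VS/UWS) or minimally conscious state (MCS).
Clinicians are asked early (1–3 months post-injury) to estimate the
probability that a patient will recover full consciousness, i.e. emerge
from MCS (eMCS: functional communication and/or functional object use).
The standard bedside instrument is the Coma Recovery Scale-Revised
(CRS-R): 23 items over six subscales — auditory (0–4), visual (0–5),
motor (0–6), oromotor (0–3), communication (0–2), arousal (0–3) — whose
total (0–23) and derived clinical diagnosis are the usual prognostic
inputs.  Both compress the six-dimensional behavioural profile to one
number or one label.

The Consciousness Domain Index (CDI) instead stratifies patients by
clustering the full subscore vector.  `cdindex` implements the CDI
end-to-end: deriving the two-cluster model from a reference cohort,
assigning external patients by nearest centroid, and comparing the CDI
with clinical diagnosis and the dichotomized CRS-R total as predictors of
recovery.

## The clustering model

Patients are points in the 6-D subscore space, on raw integer scales —
no standardization is applied, because the deployable model (shipped as
`cdi_builtin_model()`) is expressed in raw subscore units and the six
scales are already commensurate (all 0–6).  The derivation procedure,
`select_centroids_cv()`, is:

1. split the reference cohort into five seeded, unstratified folds;
2. on each training fold, fit K-means (k = 2) with K-means++ seeding and
   500 random initializations, keeping the run with minimal inertia;
3. validate each fold by the *twin-sample* approach: fit an independent
   clustering on the held-out fold, label the held-out patients under
   both models (nearest centroid under the training model; own labels
   under the validation model), and score the proportion of agreement
   after maximizing over cluster-label permutations;
4. retain the training centroids of the fold with minimal twin-validation
   error (ties go to the lowest fold index);
5. assign any new patient to the centroid nearest in Euclidean distance;
   membership in the higher-sum ("higher responsiveness") cluster is
   CDI = 1.

The choice of two clusters is supported by the mean silhouette score,
which on reference-like data is maximal at k = 2 among k = 2…6
(`silhouette_mean()`; singleton clusters contribute 0, and a = b = 0
contributes 0 by convention).

Several details of this procedure are genuinely open design choices; the
package resolves them as follows and treats them as part of its contract:

* **Best-of-500 selection** is by minimal inertia (total within-cluster
  sum of squares), standard K-means practice.
* **Lloyd convergence** is exact: iterations stop when the assignment
  vector is unchanged, with a 300-iteration cap.  At this problem size
  exactness is cheap and makes runs bit-reproducible given the seed.
* **Empty clusters** (possible with duplicate-heavy integer data) are
  re-seeded at the point farthest from the empty cluster's stale
  centroid, then iteration continues.
* **Twin-sample agreement** is permutation-matched: cluster labels are
  arbitrary across independent fits, so agreement is the maximum over the
  k! relabellings (for k = 2, `max(p, 1 - p)`, hence always ≥ 0.5).
  Without matching the statistic would be ill-defined under label
  switching.
* **CDI polarity** follows the component-sum rule, never storage order:
  `cdi_model()` relabels its inputs so CDI = 1 is the higher-sum
  centroid.  A model whose centroids have equal sums is rejected as
  degenerate.
* **Distance ties** in `assign_cdi()` go to CDI = 0, the conservative
  lower-responsiveness class.
* **Assignment-step ties** in Lloyd iterations go to the lowest cluster
  index (deterministic).

## Dichotomized comparators

The CRS-R total is dichotomized at two published cut-offs with the ≥
convention (`dichotomize_total()`): ≥ 8 (highest diagnostic accuracy for
MCS/eMCS) and ≥ 10 (highest specificity).  Together with the clinical
diagnosis (MCS vs VS/UWS) these are the comparators the CDI is evaluated
against.

## Univariate evaluation

`build_contingency()` and `diagnostic_metrics()` evaluate each binary
predictor against recovery at each follow-up.  The chi-square statistic
is the uncorrected Pearson form `n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`
with one degree of freedom; no Yates correction is applied, because the
uncorrected statistic is the one consistent with the published values
this package reconstructs from marginal counts.  Sensitivity and
specificity depend on which outcome is declared "positive" — recovery or
persistence of the pDoC — and published usage is ambiguous on this point,
so the orientation is an explicit parameter and the pipeline reports both
orientations side by side rather than deciding which was intended.
Accuracy is orientation-invariant.  A zero outcome column yields a
flagged `NA`, never a silent 0.  Reported p-values are computed exactly;
table renderings display very small values as "< 0.001".

Across-fold centroid tables report the median and IQR of each subscale's
five fold values.  Quartiles are Tukey inclusive hinges
(`stats::fivenum`): with n = 5, each half includes the median.  This
convention reproduces the shipped reference summaries cell-for-cell,
which percentile-interpolation definitions do not.

## The multivariate battery

`run_model_battery()` fits 15 logistic regressions: five predictor sets
(CDI; diagnosis; CRS-R ≥ 8; CRS-R ≥ 10; continuous CRS-R total) × three
follow-ups (6, 12, 24 months), each adjusted for age (years), sex (F
indicator against male reference), time post-injury (days) and etiology
(TBI and hypoxic-ischemic/anoxic indicators against a vascular
reference; the rare "other" etiology is folded into the reference).
Continuous covariates enter untransformed, so odds ratios are per year,
per day and per CRS-R point.

Estimation (`fit_logistic()`) is maximum likelihood via IRLS, followed by
a Newton polish with step halving until the score equations are satisfied
to `max |score| < 1e-8` (IRLS's relative-deviance stopping rule can leave
the score loose when covariates are on large scales).  Standard errors
come from the inverse observed information; per-term inference is Wald
(`wald_or_ci()`, z = 1.959964 at 95%), matching the OR-with-CI
presentation.  Rank-deficient designs are rejected with the collinear
columns named; quasi-separation (fitted probabilities at 0/1 or
|coefficient| > 15) is flagged on the fit rather than hidden — with a
strong predictor and n ≈ 143 the CIs are legitimately wide.  Model
quality is summarized by the Nagelkerke pseudo-R²
(Cox–Snell `1 − exp(2(ℓ₀ − ℓ₁)/n)` rescaled by its maximum
`1 − exp(2ℓ₀/n)`) and by the in-sample AuROC in its Mann–Whitney
formulation (ties counted ½, computed from midranks); AuROC is evaluated
on the linear predictor, which is equivalent to evaluating it on fitted
probabilities by monotone invariance.

Records missing an outcome at a given follow-up are excluded from that
follow-up's analyses only; no imputation is performed.

## The synthetic cohort generator

No patient-level data ship with the package, so `generate_cohort()`
creates cohorts with the statistical structure the analysis assumes,
making every stage testable:

* **Subscores**: a two-component mixture with means at the built-in
  reference centroids, i.i.d. Gaussian noise (σ = 0.7 per subscale),
  rounded and clipped to the subscale ranges.  This is the simplest
  integer-valued structure consistent with centroids plus dispersion;
  real subscores are correlated within patients in ways a diagonal noise
  model does not capture.
* **Mixture weight** 0.45 on the high-responsiveness cluster, and a 10%
  diagnosis flip rate so the recorded clinical diagnosis disagrees with
  the latent cluster for a minority of patients, emulating the observed
  imperfect CDI–diagnosis overlap.  Together these give ≈ 46% MCS.
* **Demographics**: age and time post-injury as rounded truncated
  normals calibrated to median/IQR 53/35 years and 56/54 days (TPI
  clipped to the 28–92-day study-entry window), 71% male, etiologies
  38.5% TBI / 24.5% hypoxic-ischemic / 37.1% vascular.  The
  rounded-normal family is a pragmatic choice; calibration is asserted by
  Monte-Carlo in the test suite rather than assumed.
* **Outcomes**: one latent uniform draw per patient compared against a
  logistic recovery probability whose linear predictor uses log-odds
  coefficients with the clinically expected directions (CDI = 1 strongly
  positive; age, female sex, TPI and anoxic etiology negative), with
  non-decreasing follow-up shifts (0, 0.23, 0.32 at 6/12/24 months).
  This yields monotone recovery — nobody relapses from eMCS — and a
  rising recovered fraction (≈ 36% → 39% → 41%).

What passing tests on these cohorts shows is that the pipeline recovers
structure *of the kind it assumes*: well-separated integer clusters,
independent noise, logistic outcomes.  They do not show robustness to
covert consciousness, medical complications, center effects or correlated
subscale noise, none of which the generator models.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and restores the
caller's RNG state; reruns are bit-identical, and the pipeline manifest
records seeds and input digests.  The test suite works at the scale the
method is used at: reference cohorts of n = 190 with 500 initializations
per K-means fit for the identifiability checks, n = 2000 × 200 replicates
for confidence-interval coverage of the logistic estimator, exhaustive
partition enumeration at n ≤ 12 as the clustering oracle, and 1000 random
tables against an observed-vs-expected chi-square oracle.

## Known limitations

* The CDI model is only as good as the reference cohort's cluster
  structure; `select_centroids_cv()` reports twin-sample accuracies
  precisely so that unstable clusterings are visible, but it will still
  return *some* centroid pair on structureless data.
* The battery's AuROC is in-sample; no cross-validated discrimination is
  computed.
* Quasi-separated models are flagged, not penalized; users wanting
  shrinkage should fit their own penalized models on the exported design.
* Item-level CRS-R administration (e.g. arousal protocols) is out of
  scope: records enter at subscore level, and the selection of the best
  of repeated assessments (by best total score) is assumed to have
  happened upstream.
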