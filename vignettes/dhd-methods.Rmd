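---
title: "Methods: risk, fairness and explainability for delayed hospital discharge"
author: "dhdrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk, fairness and explainability for delayed hospital discharge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhdrisk)
```

## Scope and model

`dhdrisk` evaluates risk models for delayed hospital discharge (DHD)
within 90 days of an acute-care admission among adults 65 and older. The
unit of analysis is the admission; patients recur, so every data split and
every cross-validation fold partitions *patients*. The package covers the
full responsible-evaluation arc — discrimination, calibration, clinical
utility, algorithmic fairness, and explainability — around two learners: a
logistic regression and a gradient-boosted tree ensemble.

Because record-level hospital data of this kind cannot be shared, the
package is organized around a synthetic cohort generator whose outcome
model is known exactly. Every downstream claim in the test suite is a
statement about recovering that known truth.

## The synthetic cohort generator

`generate_admissions()` draws, per patient: stable covariates (sex, region
on five Ontario-like labels, rural/urban residency, income quintile, four
area-level marginalization quintiles), a frailty latent `Z ~ N(0,1)`, an
age at first admission from a truncated log-normal on [65, 105] with
median ≈ 80 years, and `1 + Poisson(m - 1)` admissions dated uniformly
inside the configured year range (2004-2022). Clinical event flags (falls,
fractures, care-support need, rehabilitation discharge, palliative care)
recur per admission with logit-scale loading `0.8 * Z`, which induces the
mild positive correlation between history flags that real frailty
produces; chronic condition flags (dementia, mobility/disability,
comorbidity) switch on with the same hazard and stay on. One designated
pure-noise flag (`noise_hist`) always carries a zero coefficient so that
permutation-importance null behaviour is testable.

The outcome is drawn as `Bernoulli(sigmoid(b0 + beta' x))` where `x` is
the **look-back feature vector produced by the same builder the analysis
uses** (`build_lookback_features()`): event flags become indicators of any
occurrence on a prior admission inside a 730-day window half-open at the
index date, and chronic flags count on the index admission itself. Making
the generating features identical to the analysis features is what renders
the parameter-recovery tests well-posed; had the generator used "current"
flags while the pipeline used windowed histories, the logistic fit would
be estimating a different (attenuated) estimand.

The intercept `b0` is solved by `uniroot` so that the mean of
`sigmoid(b0 + beta' x)` over the realized covariates equals the target
prevalence (default 0.089, the published DHD admission rate). The stored
Bayes AUC is the exact pair-weighted AUC of the true probabilities,
computed from probability weights rather than sampled outcomes.

Study-condition defaults, chosen once and then frozen:

- `target_prevalence = 0.089`; subgroup shares female 0.49, rural 0.16,
  instability-Q5 0.28, dependency-Q5 0.37, deprivation-Q5 0.21,
  ethnic-concentration-Q5 0.16 — the published cohort mix.
- The coefficient map puts its largest log-odds weights on care-support
  history (1.58), dementia (1.50), rehabilitation-discharge history
  (1.14), mobility issues and fracture history (0.97), plus 0.048 per year
  of age. The overall scale was calibrated once by simulation (n = 2×10^5
  admissions) so the implied Bayes AUC is ≈ 0.82, the regime the package's
  recovery tests are specified against, and has not been revisited since.
- `mean_admissions_per_patient = 2`. A two-decade administrative cohort
  averages closer to seven admissions per patient; at desk scale that
  would multiply every row count without changing what the repeated-visit
  structure exercises (leakage guards, look-back unions), so a smaller
  value was fixed as the package's own choice.
- Contamination rates: under-65 ages 0.18, long-term-care origin 0.05,
  missing marginalization quintiles 0.003 (keeping missingness below the
  0.3% the preprocessing rules assume). Contamination is injected *after*
  outcomes are drawn, so exclusions remove corrupted rows without touching
  the truth.

What the generator does **not** emulate: informative missingness,
measurement error in the flags, secular trends in prevalence or coding
practice, regional covariate interactions, and any non-logistic outcome
mechanism. Passing recovery tests therefore certify the pipeline's
statistical machinery, not the realism of any particular clinical claim.

`generate_scored_set()` is the unit-test companion for the calibration and
fairness stages: scores `s = sigmoid(l)` with `l ~ N(logit(0.1), sigma^2)`
(`sigma` solved deterministically for a requested AUC) and outcomes
`Bernoulli(sigmoid(a_g + b_g * l))` per group, so `(a_g, b_g) = (0, 1)`
yields perfectly calibrated scores and any other pair a known logit-linear
miscalibration.

## Preparation

Exclusions run in the fixed order **age < 65 → LTC origin → any missing
field**, each row counted once under the first rule it violates, which
makes tallies deterministic and conservation (`removed + retained =
input`) checkable. Missing data are handled complete-case only; no
imputation is offered on purpose. The marginalization quintiles are
dichotomized Q5 vs Q1-Q4. The look-back window is 730 days, half-open at
the index date `[index - 730d, index)`; whether the index day itself
counts is genuinely ambiguous in the source methodology, so the boundary
was fixed as: event histories exclude the index admission, current-state
chronic conditions include it.

Two split schemes exist: random by patient (default test fraction 0.10)
and temporal by each patient's *first* admission year (≤ 2014 trains,
later tests), both asserted patient-disjoint on every run. Class imbalance
is addressed in training only — default `class_weight` (inverse-prevalence
weights), optional majority down-sampling — because altering the test
distribution would invalidate every calibration metric downstream. This
also reproduces a characteristic artifact worth knowing about: learners
trained under balanced weighting emit raw scores centred far above the 9%
prevalence, which is exactly why the post hoc calibration stage matters
and why raw-score ECE is large before Platt scaling.

## Models and tuning

`dhd_fit()` tunes by mean out-of-fold AUC over 5 folds that are grouped by
patient and stratified by the patient-level outcome. The GBT default grid
is small and documented (`max_depth` 3/5 × `eta` 0.1/0.3 × 200 rounds,
full subsampling, single thread for determinism); ties break toward fewer
rounds, then shallower trees. The logistic model is unpenalized by default
(ridge via an optional `lambda` grid), fitted on exactly the feature
matrix the generator used, which is why its coefficients are testable
against the truth within 3 standard errors at n ≈ 10^5. AUC was chosen as
the tuning objective to match the package's headline evaluation metric.

## Calibration

Platt scaling regresses the outcome on the log-odds of the score, clipped
to [1e-6, 1 - 1e-6]; the transform choice is recorded on the calibrator.
The calibration *intercept* is reported from the offset model (slope fixed
at 1) and the *slope* from the free-slope recalibration — the standard
logistic-recalibration pair, ideal (0, 1). ECE uses 10 equal-width,
count-weighted bins; the bin count is configurable and declared rather
than matched to any external convention, because published ECE values are
not comparable across unknown binning schemes. Calibrators fit on training
data by default; a held-out calibration slice is not carved out because
the evaluated workflow does not include one.

Group-stratified Platt scaling (`fit_groupwise_platt()`) is the bias
mitigation: one map per protected-group label, a global fallback for
unseen labels, and a warning-plus-fallback for single-class groups.
Because any logit-linear map is monotone for positive slopes, global Platt
provably leaves AUC and both xAUC directions unchanged (asserted to
1e-12), while stratified maps may re-order *across* groups only.

A statistical subtlety documented here because it shaped the test design:
when a group's miscalibration is exactly logit-linear, stratified Platt
inverts it completely and the group's residual ECE is pure sampling noise
(~1/sqrt(n)). A single-draw ratio of two noise-floor ECEs is heavy-tailed
and does not concentrate as n grows, so "stratified parity is closer to 1
than global parity" is asserted on ratios of *mean* per-group ECE over
independent replicates — a consistent estimate of the systematic parity —
under a study condition with a miscalibrated equity-seeking minority at a
28% share.

## Fairness audit

Protected attributes: sex (female vs male), residency (rural vs urban),
residential instability (Q5 vs Q1-4). All metrics are threshold-free.
Ratios are uniformly equity-seeking over regular; xAUC parity is forward
(equity positives vs regular negatives) over backward, and the convention
is recorded in the report since the direction is otherwise arbitrary. Ties
contribute 1/2 throughout (Mann-Whitney convention). Bands classify
`|ratio - 1|` against 0.1 and 0.2. A zero denominator ECE yields an
explicit undefined flag rather than an infinite ratio.

## Decision curves

The classification rule at threshold `t` is `score >= t` (ties act
positive). Both raw and prevalence-standardized net benefit are always
emitted: the raw scale is what the treat-all reference value ≈ -0.01 at
`t = 0.10` and 8.9% prevalence lives on, while the standardized scale has
the interpretable upper bound of 1.0 — reporting both resolves an
ambiguity between the two conventions rather than adjudicating it. The
default grid is 0.01-0.60 in steps of 0.01. Structural facts — treat-none
identically zero, treat-all crossing zero exactly at `t = pi`, model NB
bounded by `pi` — are asserted on every curve.

## Explainability

All local methods share one interventional value function: `v(S)` is the
mean model prediction over a seeded background sample with the features in
`S` fixed to the explained instance. Exact Shapley enumerates all `2^p`
coalitions and is capped at 12 features; the sampled estimator averages
marginal contributions along random feature permutations and satisfies
local accuracy *exactly* because every permutation telescopes from the
baseline to the instance prediction. Breakdown uses sequential
conditioning in a given or automatic order (decreasing absolute single-fix
effect, recomputed per instance); with a non-additive link the per-feature
terms are order-dependent while their sum is not — both facts are tested.
Local explanations default to a seeded 10% subsample of the test set, and
explanations are computed on the model's raw score scale: an attached
calibrator is a monotone rescale that preserves which features drive a
prediction, and the high-risk stratum (score > 0.5) is meaningful on the
raw scale of a class-weight-trained model.

## Explanation clustering

Per high-risk instance, features are ranked by decreasing absolute
contribution with lexicographic tie-breaks for determinism; the summary
per feature is the signed mean contribution, mean rank, and the percentage
of high-risk patients with the feature in their top 10. The three columns
are z-scored and eigendecomposed via the 3×3 correlation matrix; sign
indeterminacy is resolved by forcing the contribution loading nonnegative
on each component; quadrants follow the signs of the PC1/PC2 scores, and
the a-priori category map (sociodemographic-geographic,
multimorbidity-health, mobility-disability; editable CSV in
`inst/extdata/`) is tabulated within quadrants. Signed means with
absolute-value ranking is a declared convention — averaging absolute
contributions instead would conflate protective and aggravating effects.

## Problem sizes and numerical choices

The test suite exercises: generator recovery and learner recovery at
~10^5 admissions (50,000 patients); calibration and fairness recovery on
scored sets of 2-10 × 10^4; oracle equivalences (brute-force AUC/xAUC
enumeration up to n = 200, full coalition enumeration up to 5 features,
power-iteration eigensolver) at desk scale; and one end-to-end pipeline
run on a ~50,000-admission cohort. These sizes were chosen so Monte-Carlo
tolerances (3-4 standard errors) dominate the assertions rather than
runtime. Probabilities are clipped at 1e-6 before any logit; exact-method
identities are asserted at 1e-10-1e-12; eigen agreement at 1e-8.

## Limitations

- The generator's logit-linear distortions are exactly invertible by Platt
  scaling; real miscalibration rarely is, so mitigation results here are a
  best case.
- PDP and permutation importance inherit their usual correlated-feature
  caveats; the frailty latent deliberately induces such correlation so the
  caveat is visible, not hidden.
- The explanation subsample must contain high-risk instances; tiny cohorts
  should raise `subsample_fraction` or lower `risk_threshold`.
- Nothing here validates any claim about real-world discharge data; the
  package validates machinery, and its synthetic defaults are labelled as
  such throughout.
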