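---
title: "Methods: education, neuropathological burden, and cognition in memory-clinic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: education, neuropathological burden, and cognition in memory-clinic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Education is one of the strongest correlates of cognitive performance in
aging, and a standard proxy for cognitive reserve. In a memory-clinic
population, two moderation questions arise. *Across* diagnoses: does the
association between education and cognition weaken as clinical severity
increases from subjective cognitive decline (SCD) through mild cognitive
impairment (MCI) to Alzheimer's dementia (AD)? *Within* a diagnosis: does
the association depend on how much neurodegeneration a patient carries,
summarized from visual MRI ratings? `cogreserve` implements the full
cross-sectional analysis pipeline for these questions — scoring, a
composite neuropathology burden score, the interaction inference, and the
descriptive and sensitivity machinery around it — together with a synthetic
cohort generator so that every stage is testable without patient data.

## Compound cognitive scoring

Raw test scores (MMSE, VAT, 8-Word immediate and delayed recall, verbal
fluency, FAB, TMT part A, and the TMT B/A ratio) are z-standardized against
the whole study sample using the sample SD (n−1 denominator; the
convention had to be fixed and the n−1 sample convention is standard for
sample z-scores). The two timed TMT variables are then negated so that
higher z always means better performance; both TMT part A and the TMT ratio
are inverted. Participants unable to complete TMT part B receive the lowest
(worst) z-score observed among completers, on the inverted ratio scale.

The fixed order of operations is: compute the B/A ratio, standardize,
invert, floor. The floor rule is read as "the sample minimum of the final
inverted z", which changes values relative to other readings, so the order
is part of the documented contract (`score_cohort()`), and the rule is
idempotent by construction.

Compound scores are the mean of the participant's *available* contributing
test z-scores: global cognition uses all eight contributors, episodic
memory uses VAT plus the two 8-Word recalls, executive functioning uses
fluency, FAB and the TMT ratio. The immediate and delayed 8-Word recalls
enter as separate sub-tasks. A domain is missing only when all of its
contributors are missing; models then drop that participant listwise, and
every model reports the n actually used. The Verhage education scale (1–7)
collapses to low (1–3), average (4–5) and high (6–7).

## The neuropathological burden score

Three visual ratings — medial temporal atrophy (MTA, 0–4), global cortical
atrophy (GA, 0–3) and white matter hyperintensities (WMH/Fazekas, 0–3) —
are combined into one cognition-relevant burden score per cognitive domain:

1. Regress the domain score on (MTA, GA, WMH) by OLS.
2. To keep the score from being dominated by the larger diagnosis groups,
   embed the regression in a stratified bootstrap: across 100 replications,
   draw 75 cases from each diagnosis group and fit on the pooled 225.
3. Within each replication, retrieve parameters by leave-one-out
   cross-validation: fit the OLS model n times leaving out one observation,
   and average the n parameter vectors. The package computes this with the
   exact closed-form downdate
   $\hat\beta_{(i)} = \hat\beta - (X'X)^{-1} x_i \hat e_i / (1 - h_i)$,
   verified in the tests against a brute-force refit loop.
4. Average intercepts and weights across replications, then *invert* the
   fitted linear predictor: burden = −(intercept + w·x), so higher burden
   means more neurodegeneration relevant to that domain. The burden score
   is finally z-standardized across the analysis sample, which makes the
   intercept inconsequential downstream (tested).

Interpretive choices we had to fix: "optimal parameters by LOOCV" is read
as averaging the leave-one-out parameter vectors — for OLS with no
hyperparameter this is the only parameter-producing reading; the
alternative (plain OLS per bootstrap replication) is available as
`method = "full_ols"` for comparison. Sampling within groups is without
replacement (75 < 108, the smallest group), switchable via `replace`.
Ratings enter the regression on their raw ordinal scale; the weights absorb
the scale.

## The inference battery

All model variables are z-scored on the rows entering each model, after
listwise deletion. Education enters as the 3-level category coded 1/2/3 and
then z-scored — a single numeric education slope per model. Sex stays a
binary indicator: z-scoring a binary changes nothing inferentially and
costs interpretability.

*Across diagnoses.* An ANCOVA per domain regresses the domain score on
z(education) × diagnosis plus z(age), sex, and z(burden); the interaction
block is tested with a nested-model F with numerator df = levels − 1 = 2.
Stratified models per group then estimate the education slope, adjusted for
age, sex, and the domain's burden, and slopes are compared pairwise with
Welch t-tests, $t = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$, with
Welch–Satterthwaite df built from each model's residual df. All three pairs
(SCD–MCI, SCD–AD, MCI–AD) are computed.

*Within diagnoses.* Per group and domain, the model
y ~ z(edu) + z(burden) + z(edu)·z(burden) + z(age) + sex is fitted. The
interaction term is the product of the two z-scored mains, deliberately
left unstandardized: that makes the simple-slope algebra exact,
slope(m) = b_edu + m·b_int at burden = m SD, with
SE²(m) = Var(b_edu) + m²Var(b_int) + 2m·Cov. The tests verify this against
a refit with the moderator re-centred at ±1 SD — an exact identity, not an
approximation. An unadjusted variant (`adjusted = FALSE`) is available
because the covariate set of the within-group models is a reporting choice.

Effect sizes are Cohen's f² = (R²_full − R²_reduced)/(1 − R²_full) with the
conventional 0.02/0.15/0.35 thresholds. Multiplicity is controlled by
Benjamini–Hochberg FDR within four explicit families: (A) the three ANCOVA
interactions, (B) the nine stratified education effects, (C) the slope
comparisons, (D) the nine education×burden interactions. Published analyses
of this design rarely state their families, yet "did not survive FDR"
claims depend entirely on them — so the family is an explicit, labeled
argument and raw p-values are always reported alongside.

## Descriptives and sensitivity analyses

`summary_table()` reproduces the usual characteristics table: medians (IQR)
with Kruskal–Wallis omnibus and Mann–Whitney post-hocs for ordinal or
skewed variables (age, education, ratings), means (SD) with ANOVA and Welch
post-hocs for the compound scores, counts (%) with chi-squared tests for
categoricals; post-hoc p-values are BH-adjusted within each variable, and
omnibus p-values across variables. The variable→test mapping is declared,
not inferred. Rank tests use exact enumeration for small tie-free samples
and midrank normal approximation with continuity correction otherwise (the
`wilcox.test` defaults, validated against an enumeration oracle).

Three sensitivity variants re-run the same code paths under altered inputs:
(1) norm-score compounds, standardizing each test against an age-band ×
education-category normative cell instead of the whole sample — because the
cells condition on education, education effects are expected to attenuate;
(2) reduced compounds without the two floor-prone sub-tests (TMT ratio,
delayed recall); (3) single-rating moderators, replacing the composite
burden with z(MTA), z(GA) or z(WMH) in the interaction while adjusting for
the other two ratings, with a "driver" flagged per cell as the
largest-magnitude interaction among those with uncorrected p < 0.05 (a
definition we fix because drivers are usually reported without one). Each
report carries a concordance summary (sign flips, significance agreement)
against the main analysis.

The normative table shipped by `synthetic_norm_table()` is entirely
synthetic: cell means/SDs of a large simulated healthy reference sample
drawn under a fixed internal seed. It mimics the *structure* of population
normative databases, not their content.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes. Defaults emulate a 543-patient memory clinic cohort
(108/190/245 across SCD/MCI/AD):

* **Ages** come from two-piece Gaussians matched to per-group median and
  quartiles (e.g. SCD 71 with IQR 66–78), rounded to whole years — a
  transparent way to reproduce skewed clinical age distributions.
* **Education and ratings** are drawn from per-group categorical
  distributions chosen so that large-sample medians match the documented
  targets (`cohort_marginal_targets()`) exactly and IQR endpoints to within
  one unit; categorical draws (not discretized Gaussians) keep that
  calibration transparent and testable.
* **Rating dependence** uses a Gaussian copula with Spearman rank
  correlation 0.4 between MTA, GA, WMH — a free parameter of the generator,
  since joint rating distributions are essentially never published.
* **Latent domain scores** follow
  y = μ(group) + w·ratings + β·z(edu) + γ·z(edu)·z(burden) +
  a·z(age) + s·male + ε, with pathology weights around −0.3…−0.1 per rating
  point, residual SD 0.5, and per-group education slopes (0.60/0.35/0.15 on
  global cognition) and episodic-memory interactions (−0.23 in SCD, +0.15
  in MCI) matching the magnitudes this literature reports. Covariate
  standardization is within-group, so within-group regressions recover the
  generating slopes directly (tested at n = 5000 within 2 Monte-Carlo SEs).
* **Raw tests** are affine maps of their domain latent plus test noise,
  rounded and clipped to instrument ranges; clipping counts are recorded
  because clipping induces exactly the floor effects that motivate the
  reduced-compound sensitivity analysis. TMT-B non-completion is logistic
  in the group-centred latent executive score with per-group offsets,
  concentrating non-completion in MCI/AD and in poor executive performers
  (about 7/40/65 expected non-completers per group).

One seeded RNG stream drives a fixed, documented draw order (per group:
age, sex, education, ratings; then domain noise, test noise, completion),
so adding a downstream field never reshuffles earlier draws; the generator
restores the caller's RNG state.

What the generator does *not* emulate: item-level responses, measurement
non-linearity beyond clipping, missing clinical covariates, informative
missingness beyond TMT-B, diagnosis misclassification, or longitudinal
change. Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* is correct and well-calibrated under the assumed data-generating
structure — not that the substantive findings hold in any real population.

## Numerical choices and degenerate inputs

Zero-variance variables are explicit errors in standardization; in the
*generator*, a degenerate covariate (single education level, constant age)
contributes zero effect instead, so noiseless calibration cohorts are
constructible. `loocv_average_fit()` refuses rank-deficient designs and
leverage-one observations (1 − h < 1e−10), where a leave-one-out fit is
unidentifiable. Burden fitting requires every group to hold at least
`per_group_draw` complete cases and names the offending group otherwise.
Quantiles of ordinal variables use the inverse-CDF definition (type 1), the
natural choice for discrete scales. f² at a numerically perfect fit
(R² = 1, arising only in noiseless validation data) is reported as
infinite rather than an error.

## Problem sizes used by the test suite

The acceptance properties run at the study's group sizes (108/190/245):
size calibration of the interaction tests uses 1000 simulated null cohorts
(25 burden replications each; replication count affects runtime, not test
size), pattern recovery uses 500 cohorts with the full 100 replications,
burden-weight recovery uses one n = 2000 cohort with 100 × 300-per-group
replications, and the oracle suites use 100 random OLS/ANCOVA fixtures,
1000 random p-vectors, and 50 simple-slope fixtures. Marginal calibration
of the generator is checked at 20× the default group sizes.

## Known limitations

The package analyses cross-sectional data only; no causal or longitudinal
claims are supported. The burden score is a linear, visual-rating-based
summary — no volumetric, voxel-wise or regularized alternatives. The
FDR-family definitions, the LOOCV-averaging reading, the raw-ordinal
treatment of ratings, and the education coding are documented choices;
where a published analysis made different choices, results can differ even
on identical data, which is precisely why each is surfaced as an explicit
argument.
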