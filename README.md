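# cogreserve

Education is the classic proxy for cognitive reserve: better-educated
people tend to perform better cognitively at the same age, sometimes even
at the same level of brain pathology. Whether that protection survives
clinical deterioration is an open question in memory-clinic populations.
`cogreserve` implements a complete cross-sectional moderation analysis for
cohorts spanning subjective cognitive decline (SCD), mild cognitive
impairment (MCI) and Alzheimer's dementia (AD), for biostatisticians and
neuropsychology researchers who want the whole pipeline — scoring, burden
construction, inference, descriptives, sensitivity analyses — as tested,
reusable code rather than a one-off script.

## What it computes

**Compound cognitive scores.** Raw neuropsychological tests (MMSE, VAT,
8-Word immediate/delayed recall, verbal fluency, FAB, TMT-A, TMT B/A
ratio) are z-standardized against the whole sample, timed tests inverted so
higher z is better, TMT-B non-completers floored at the worst completer z,
and averaged into three domains: global cognition, episodic memory,
executive functioning.

**A cognitive-domain-specific neuropathology burden score.** Per domain,
the score is built by regressing cognition on three visual MRI ratings
(MTA 0–4, GA 0–3, WMH 0–3) under a diagnosis-stratified bootstrap (100
replications × 75 cases per group) with leave-one-out cross-validated
parameter averaging, then inverting the averaged predictor:

    burden = −(â + ŵ_mta·MTA + ŵ_ga·GA + ŵ_wmh·WMH),  z-scored

so that higher burden means more cognition-relevant neurodegeneration.

**Moderation inference.** Education×diagnosis ANCOVA interactions (nested
F), diagnosis-stratified education slopes adjusted for age, sex and burden,
pairwise Welch t comparisons of those slopes, education×burden interaction
models per group with exact simple slopes at −1/0/+1 SD of burden
(slope(m) = β_edu + m·β_int), Cohen's f², and Benjamini–Hochberg FDR within
explicit, user-visible test families.

**Synthetic cohorts.** Because clinical datasets of this kind are not
publicly deposited, `generate_cohort()` draws fully synthetic cohorts with
calibrated marginals (ages, Verhage education 1–7, ordinal ratings under a
Gaussian copula) and configurable generating education slopes and
interactions, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(cogreserve)

spec   <- default_sim_spec(seed = 7)         # 543 patients: 108/190/245
cohort <- generate_cohort(spec)
scored <- score_cohort(cohort)               # compounds + education category
wb     <- add_burden_scores(scored, seed = 7)
wb$models$global_cognition
#> Neuropathology burden model for global_cognition
#>   100 replications x 75 cases/group (loocv, without replacement)
#>   intercept 1.1718; weights mta=-0.4397, ga=-0.2152, wmh=-0.1661
```

All three rating weights are negative — more atrophy or more white-matter
damage predicts worse global cognition — so the inverted burden score rises
with neurodegeneration.

```r
res <- run_moderation_analysis(wb$scored)
res$ancova
#>             domain         F df1 df2        p_raw   n          f2        p_fdr
#> 1 global_cognition 13.825188   2 534 1.399843e-06 543 0.051779729 2.099765e-06
#> 2  episodic_memory 18.030999   2 534 2.644342e-08 543 0.067531830 7.933026e-08
#> 3        executive  1.628697   2 534 1.971581e-01 543 0.006099989 1.971581e-01

res$stratified[res$stratified$domain == "global_cognition",
               c("group", "beta_edu", "se", "p_fdr")]
#>   group  beta_edu         se        p_fdr
#> 1   SCD 0.4806987 0.05660587 1.464398e-12
#> 2   MCI 0.3817245 0.05001902 5.361143e-12
#> 3    AD 0.1981822 0.05091937 1.774018e-04
```

The education–cognition association weakens monotonically with diagnosis
severity (standardized slopes 0.48 → 0.38 → 0.20), exactly the pattern the
generator injects (0.60/0.35/0.15 before attenuation by test noise). Within
groups, the education×burden interaction on episodic memory is negative in
SCD and positive in MCI:

```r
res$interactions[res$interactions$domain == "episodic_memory",
                 c("group", "beta_int", "p_raw")]
#>   group      beta_int        p_raw
#> 4   SCD -2.013507e-01 0.0015682737
#> 5   MCI  2.110895e-01 0.0002964349
#> 6    AD -3.712278e-05 0.9993610197

res$simple_slopes[res$simple_slopes$domain == "episodic_memory" &
                  res$simple_slopes$group == "SCD", c("level", "slope", "p")]
#>    level     slope            p
#> 10    -1 0.6318868 1.258662e-09
#> 11     0 0.4305361 2.311684e-09
#> 12     1 0.2291855 8.837697e-03
```

In SCD, education relates to memory most strongly at *low* burden
(slope 0.63 at −1 SD, shrinking to 0.23 at +1 SD); in MCI the gradient runs
the other way — the qualitative signature of reserve effects that depend on
where a patient sits in the disease course.

Everything can also be run in one call, writing CSVs, burden JSON,
descriptive tables, sensitivity reports and a reproducibility manifest:

```r
run_pipeline(run_config(spec = default_sim_spec(), seed = 7,
                        out_dir = "results_run"))
```

A thin command-line wrapper lives in `inst/scripts/run_pipeline.R`.

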