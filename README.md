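# spousim

Spouses resemble each other in cardiometabolic risk factors — blood
pressure, lipids, glycaemia, adiposity, smoking, drinking, physical
activity and the diseases built on them. Two mechanisms can produce that
resemblance: partner choice and shared environment (assortative mating and
cohabitation), or the mundane fact that spouses are close in age while most
risk factors track age. `spousim` implements the analysis that separates
the two: it compares spouse pairs against **exact-age-matched random
male–female pairs**, a permutation null in which every man is re-assigned a
woman of exactly his wife's integer age. Any similarity that survives in
the random pairs is attributable to age structure alone; similarity present
only in spouse pairs points to couple-specific mechanisms.

The package is aimed at epidemiologists who want to run this design on
their own couple cohorts, and — because couple-linked biobank data are
typically access-restricted — it ships a calibrated synthetic couple-cohort
generator so every stage is testable and demonstrable without restricted
data.

## What it computes

* **Synthetic cohorts** (`generate_cohort()`, `default_config()`): couples
  with correlated integer ages (men 63.2 (SD 10.5) years, women 60.4
  (SD 10.2), spousal age correlation 0.934 by default), sex-specific trait
  distributions, a per-couple latent factor injecting residual spousal
  correlation `couple_corr` per trait, logistic lifestyle traits with a
  shared-couple log odds ratio, thresholded medication assignment and MCAR
  missingness.
* **Harmonization** (`derive_all()`): BMI; Friedewald LDL
  (`tc − hdl − tg/5`, invalid at TG ≥ 400 mg/dL); medication
  back-adjustment (+15/+10 mmHg to treated SBP/DBP; treated TC and LDL
  divided by 0.8 and 0.7); log10 triglycerides; outlier exclusion beyond
  mean ± 5 SD per variable per sex; hypertension, type 2 diabetes and
  metabolic-syndrome flags; activity cut-off at the 80th percentile of the
  men's MET hours/day; education recode.
* **The null pairing** (`exact_age_shuffle()`): a Fisher–Yates permutation
  of wives within exact-age strata, preserving every husband's partner age
  — and therefore the male–female age correlation bit-for-bit.
* **Similarity** (`pair_correlation()`): within-pair Pearson correlations,
  simple and age-adjusted (sex-stratified OLS residuals on age), with
  Fisher-z intervals `tanh(atanh(r) ± z/√(n−3))`.
* **Concordance** (`fit_concordance()`): logistic regression of the male
  partner's binary status on the female's, crude and adjusted for the
  pair's mean age and age difference; Wald intervals; odds ratios above 1
  indicate concordance.
* **Reporting** (`describe_cohort()`, `run_pipeline()`): a baseline
  characteristics table with chi-square / pooled-t / Mann–Whitney group
  tests, and a one-call pipeline writing all tables as CSV for both
  pairings.

## Worked example

```r
library(spousim)

cohort <- generate_cohort(default_config(), seed = 1)   # 5,391 couples
spouse <- derive_all(cohort)
random <- spouse
random$pairs <- exact_age_shuffle(cohort, seed = 2)$pairs

pair_correlation(spouse, "height")[, c("r_simple", "r_adjusted")]
#>   r_simple r_adjusted
#> 1    0.286      0.185
pair_correlation(random, "height")[, c("r_simple", "r_adjusted")]
#>   r_simple r_adjusted
#> 1    0.120   -0.00529

fit_concordance(spouse, "current_smoker")[, c("crude_or", "adjusted_or")]
#>   crude_or adjusted_or
#> 1     5.07        4.64
fit_concordance(random, "current_smoker")[, c("crude_or", "adjusted_or")]
#>   crude_or adjusted_or
#> 1     1.17        1.02
```

Read it as the design intends. Height: spouses correlate at 0.29, but part
of that is age (cohort effects in stature); the random age-matched pairs
keep a simple correlation of 0.12 that vanishes (−0.005) once age is
residualised — while the spouse pairs retain 0.185, the couple-specific
component the generator injected. Smoking: spouse concordance is strong
(adjusted OR 4.64, 95% CI 3.59–5.99) but the random pairs show none
(adjusted OR 1.02) — their small crude elevation (1.17) is purely the
shared age trend in smoking prevalence, and adjustment removes it.

The same analysis end-to-end, with all tables written as CSV:

```r
run_pipeline(default_config(), seed = 1, outdir = "out")
```

or from a shell via `inst/scripts/spousim-cli.R`
(`simulate`, `derive`, `shuffle`, `analyze`, `report`, `all` subcommands).

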