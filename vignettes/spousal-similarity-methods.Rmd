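---
title: "Methods: age-matched permutation nulls for spousal similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-matched permutation nulls for spousal similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Married partners are alike in cardiometabolic risk factors. Assortative
mating (people choose similar partners) and cohabitation (partners converge
through shared environment and mutual influence) both predict genuine
couple-level similarity. But spouses are also close in age, and nearly
every cardiometabolic trait drifts with age, so some observed similarity
is an age artefact. The design implemented here disentangles the two by
constructing a **covariate-matched permutation null**: women are shuffled
among couples *within strata of exact integer age*, so every man's new
partner has precisely his wife's age. The joint age distribution of pairs
— including the male–female age correlation — is preserved exactly, while
all couple-specific links are severed. Estimates on the randomized pairing
isolate what age structure alone produces; the spouse-minus-random gap is
the couple-specific signal.

Two estimators are applied to both pairings:

* continuous traits: the within-pair Pearson correlation, simple and
  **age-adjusted** — each sex's values are replaced by residuals from a
  sex-specific ordinary least-squares regression on age before
  correlating. Intervals use the Fisher z transform,
  $\tanh\!\left(\operatorname{atanh} r \pm z_{1-\alpha/2}/\sqrt{n-3}\right)$.
* binary traits: logistic regression of the male partner's status on the
  female partner's, crude and adjusted for the pair's **mean age**
  $(a_m+a_f)/2$ and **age difference** $a_m-a_f$ (together an invertible
  reparameterisation of the two ages). Odds ratios are exponentiated
  coefficients with Wald intervals.

## Harmonization rules

Raw records are turned into analysis variables by `derive_all()`:

* **BMI** = weight (kg) / height (m)².
* **LDL cholesterol** by the Friedewald combination
  `tc − hdl − tg/5` (mg/dL) when no direct value is present, declared
  invalid (missing) at triglycerides ≥ 400 mg/dL. The bound is the
  standard clinical validity restriction; it is configurable.
* **Medication back-adjustment**: for individuals on antihypertensive
  treatment, +15 mmHg (SBP) and +10 mmHg (DBP); for individuals on
  lipid-lowering treatment, TC ÷ 0.8 and LDL ÷ 0.7. The purpose is to
  reconstruct the pre-treatment population ranking for correlation
  analysis; *disease* flags use the measured values, where medication use
  itself already counts as criterion fulfilment. An unknown treatment flag
  makes the adjusted value missing.
* **Triglycerides** are log10-transformed for correlation analysis (their
  distribution is right-skewed).
* **Outliers**: per variable and per sex, values beyond mean ± 5 SD are
  set to missing. The mean and SD are computed in a single pass over all
  non-missing values — not iterated after exclusions — which avoids
  order-of-iteration ambiguity. Exclusion happens after the treatment
  back-adjustment and before analysis; the ordering is a package decision,
  as either order is defensible.
* **Diseases**: hypertension (SBP ≥ 140 or DBP ≥ 90 mmHg or medication);
  type 2 diabetes (HbA1c ≥ 6.5% or medication); metabolic syndrome by the
  Japanese criteria — mandatory waist circumference (≥ 85 cm men, ≥ 90 cm
  women) plus at least two of blood pressure ≥ 130/85 or medication,
  HbA1c ≥ 6.0% or medication, TG ≥ 150 mg/dL or HDL < 40 mg/dL or
  medication. A flag is missing whenever *any* required component is
  missing, even if observed components would already decide it, so each
  disease's analysis set contains only fully assessable individuals.
* **HbA1c eligibility**: individuals on glucose-lowering medication are
  excluded from HbA1c correlation analyses (treatment alters HbA1c), via
  an explicit eligibility flag.
* **Physical activity**: the cut-off is the 80th percentile of the men's
  MET hours/day, applied to both sexes; "sufficiently active" uses the
  closed inequality (≥). Percentiles interpolate linearly between order
  statistics (0-based index (p/100)(n−1), R's type-7 default); the
  definition is swappable.
* **Education** is recoded low / medium / high, with "other" treated as
  missing.
* **Smoking/drinking contrasts** pool past and never into "non-current".

Pair filtering is **pairwise-complete per variable**: a pair is dropped
from one variable's analysis when either member lacks that variable, which
is why each table row has its own n. The age-residual regressions are
fitted on exactly the individuals entering that variable's analysis, after
outlier exclusion. The adjusted correlation's interval reuses the n−3
Fisher formula without a degrees-of-freedom correction for the two age
regressions; at the intended sample sizes (thousands of pairs) the
approximation is negligible, and it is documented rather than hidden.

## The re-pairing algorithm

`exact_age_shuffle()` groups the paired women by integer age, processes
strata in ascending age order, and applies a Fisher–Yates permutation
(`sample.int`) to each stratum's members, reassigning them to that
stratum's husbands in original pair order. One seeded generator drives the
whole shuffle, so `(cohort, seed)` determines the output completely.
Consequences worth stating:

* the multiset of (male age, female age) pairs — indeed each husband's
  partner age — is invariant, so the pairwise age correlation is
  *bit-for-bit identical* between pairings (a test asserts this);
* a re-paired couple may coincide with the original spouse pair; such
  coincidences are allowed, not rejected — rejection would bias the
  permutation distribution away from uniform;
* women with a unique age necessarily keep their partner;
* matching is on exact integer age with no tolerance window (a tolerance
  would break the exact-preservation property that makes the null clean).

A single realization is the default, mirroring how such analyses are
usually reported; because the analysis functions are pure, callers can
trivially repeat the shuffle over seeds to quantify Monte-Carlo spread.

## The synthetic cohort generator

Couple-linked human data are access-restricted almost everywhere, so the
package treats the generator as a first-class, tested component rather
than a test fixture. It emulates a community cohort of older Japanese
couples; the defaults in `default_config()` are fixed study conditions,
not tuning knobs.

**Ages.** Bivariate normal (men 63.2, SD 10.5; women 60.4, SD 10.2;
correlation 0.934), rounded to whole years — questionnaire ages are whole
years, and the pairing algorithm matches on exact integer age. Couples
with a member under 20 (the eligibility bound) are redrawn entirely rather
than clipped, avoiding a point mass at 20. Rounding adds 1/12 of a year² of
variance, attenuating the realized age correlation by well under 0.001.

**Continuous traits.** For each trait and sex, the value is
`mean + slope · (age − age_mean) + residual`. The residual is split
between a per-couple latent factor carrying a fraction `|couple_corr|` of
the residual variance (sign handled by flipping the factor's loading for
one member) and individual noise, so the marginal SD equals the configured
SD and the *residual* spousal correlation equals `couple_corr`. A single
latent factor per couple per trait is the simplest structure separating
assortment/cohabitation similarity from age-driven similarity. Default
means/SDs follow the emulated cohort (e.g. weight 66.5 (9.6) / 54.1 (8.7)
kg; SBP 129.7 (16.3) / 125.9 (17.7) mmHg); default `couple_corr` values
are set to that cohort's age-adjusted spousal correlations (0.073–0.175).
Age slopes are chosen so that the *simple* spousal correlations also land
near their observed values given the 0.934 age correlation — e.g. height
at −0.20 cm/year (secular cohort trend) turns an adjusted 0.175 into a
simple ≈ 0.29. Triglycerides and MET hours/day are simulated normally on
the log10 scale and back-transformed, which keeps them positive and
right-skewed; their config entries are log10-scale means/SDs derived from
medians and interquartile ranges (e.g. TG medians 104 and 88 mg/dL).

**Binary lifestyle traits.** The female partner's status is drawn from a
sex-specific logistic age model; the male's linear predictor adds
`couple_log_or · (y_f − p_f(age_f))`. Centring on the female's expected
status keeps the male marginal prevalence at its configured level while
making `couple_log_or` exactly the conditional within-couple log odds
ratio, which the adjusted concordance model then recovers. Defaults:
current smoking at 20.8% / 4.7% with negative age slopes and couple log-OR
log(4.60); current drinking at 78.4% / 40.8% with couple log-OR log(2.83).
Among non-current individuals, past vs never status is split by fixed
sex-specific probabilities with no couple effect.

**Medication and the invertibility contract.** Treatment is a thresholded
Bernoulli on the *pre-treatment* value: antihypertensive medication with
probability 0.7 when SBP ≥ 140 or DBP ≥ 90 mmHg; lipid-lowering with
probability 0.5 when TC ≥ 240 mg/dL; glucose-lowering with probability 0.6
when HbA1c ≥ 6.0%. The stored *measured* values of treated individuals are
attenuated by exactly the harmonization constants (SBP −15, DBP −10 mmHg;
TC ×0.8, LDL ×0.7), so the back-adjustment recovers pre-treatment values
exactly — a deliberate design making the adjustment rules invertible and
testable (treated individuals' adjusted values must sit back above their
treatment gates, and they do). Two consequences are documented rather than
papered over: measured means of SBP/DBP/TC sit slightly below the
configured (pre-treatment) means — the calibration tests therefore check
the back-adjusted values — and prevalences driven by medication are
approximate. The glucose gate sits at the hyperglycaemia threshold 6.0%
rather than the diagnostic 6.5% because most people under treatment have
controlled HbA1c below 6.5; gating at 6.5 would produce a diabetes
prevalence of ~2% against the ~15%/7% (men/women) seen in the emulated
population, leaving concordance tables degenerate. With the 6.0 gate the
default cohort lands near 10%/7%.

**Missingness** is independent per variable (MCAR), with default rates set
to roughly reproduce the per-variable availability of the emulated cohort
(e.g. waist 23%, total cholesterol 40%, blood pressure 2.7%, medication
flags 8%). No missingness *mechanism* was available to emulate, and under
MCAR the per-variable rates cannot simultaneously reproduce the ns of
composite disease flags (which need many components at once); the
metabolic-syndrome analysis set is therefore smaller than in the emulated
cohort. No imputation is performed anywhere.

**What the generator does not emulate.** Recruitment structure, geography,
non-spousal family links, measurement error correlated across traits,
informative missingness, treatment effects on HbA1c, and age-varying
couple effects. Passing tests therefore demonstrate that the *estimators
and the permutation null behave correctly* under a known data-generating
process — not that any particular real-world estimate is reproduced.

## Numerical and inferential choices

* Pearson correlations are computed by the standard product-moment
  formula; a from-scratch sum-based oracle agrees to 1e−12 in tests.
* `atanh(±1)` is infinite, so a correlation of exactly ±1 returns a
  degenerate point interval rather than NaNs.
* Logistic fits use iteratively reweighted least squares with a tightened
  convergence tolerance (1e−12) so the crude fit matches the closed-form
  2×2 cross-product odds ratio to 1e−8. Non-convergence and separation
  (runaway coefficient or standard error) raise errors naming the outcome;
  no continuity correction is applied silently — sparse tables fail
  loudly.
* Wald (not profile-likelihood) intervals are reported for odds ratios,
  matching standard epidemiological reporting.
* Group tests in the descriptive table: Pearson chi-square without
  continuity correction; pooled-variance Student t; Mann–Whitney U by
  normal approximation with tie correction (intended for thousands of
  pairs, where the exact test is unnecessary). Zero-variance comparisons
  yield a missing p-value rather than an error.
* Rounding (1 decimal place for percentages and summaries) happens only in
  the reporting layer; all internal computation is full precision.
* Every stochastic function takes an explicit seed, restores the caller's
  RNG state, and is bit-reproducible given `(input, seed)`. The pipeline
  uses `seed` for generation and `seed + 1` for the shuffle.
* The adjusted concordance model uses the same covariates (pair mean age,
  age difference) for both pairings; for the spouse pairing these are the
  same quantities by construction of the shuffle.

## Problem sizes in the test suite

The suite exercises the estimators at the sizes where their guarantees are
sharp but cheap: calibration and recovery checks at 5,000 couples,
null-coverage over 200 replicates of 250 couples, type-I error of the
adjusted concordance test over 400 replicates of 500 couples, power
monotonicity over 40 replicates at 800 couples, and shuffle uniformity
over 6,000 seeded permutations of a three-member stratum. Full-size
(5,391-couple) runs appear in the acceptance script and the end-to-end
tests. These sizes are the package's own choices balancing Monte-Carlo
resolution against suite runtime.

## Known limitations

* The Fisher interval for the *adjusted* correlation ignores the two
  degrees of freedom spent on the age regressions.
* The permutation null is built for one matching covariate (age); the
  design generalises to other covariates only by replacing the strata.
* MCAR missingness is a simplification; estimates under informative
  missingness are not studied here.
* Single-realization shuffles carry Monte-Carlo noise; repeat over seeds
  when the spouse-minus-random contrast is near the decision boundary.
* No multiple-testing correction is applied across the trait panel, by
  design of the emulated analysis.
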