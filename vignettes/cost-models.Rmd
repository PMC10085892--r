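---
title: "Annual healthcare cost models for cardiovascular events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual healthcare cost models for cardiovascular events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdcost)
```

## The models

`cvdcost` evaluates two families of individual-level annual healthcare cost
models for UK adults, estimated separately for people without and with previous
cardiovascular disease (CVD) at study entry, with all monetary values in 2020
UK pounds.

**Primary care costs** follow a one-part generalised linear model with Poisson
variance and identity link. Under the identity link the linear predictor *is*
the expected annual cost, so each coefficient is an additive amount in pounds:
the intercept is the annual cost of the reference individual, and, for example,
the incident-MI coefficient is the extra annual primary care cost in every year
from the MI onwards. The Poisson variance assumption (variance proportional to
the mean) only affects weighting and inference, not the additive
interpretation; fitting is by quasi-likelihood, so non-integer responses are
unproblematic.

**Hospital inpatient costs** have a large spike at zero (most people are not
admitted in a given year) and a long right tail, so they follow a two-part
model: a logistic regression for the probability of incurring any cost in the
annual period, and an identity-link Poisson GLM for the cost conditional on
incurring any. The expected annual cost multiplies the two parts:

\[
\text{Odds} = \exp\Big(\ln(\text{odds}_0) + \sum_i \ln(\mathrm{OR}_i)\,x_i\Big),
\qquad
E[\text{cost}] = \frac{\text{Odds}}{1+\text{Odds}} \times
\Big(\gamma_0 + \sum_i \gamma_i x_i\Big).
\]

One certainty rule overrides part 1: in an annual period containing a coronary
revascularization (CRV), incurring hospital cost is treated as certain
(probability exactly 1) — a revascularization is itself an admission.

**Covariates.** Baseline: sex, ethnicity, Townsend deprivation quintile,
smoking, physical activity, diet quality, BMI category, LDL (centred at 3.6,
per mmol/L), ln HDL, ln creatinine (centred at 4.4, per 0.2 ln umol/L),
systolic (centred 140, per 20 mmHg) and diastolic (centred 80, per 10 mmHg)
blood pressure, antihypertensive treatment, severe mental illness, prior
type 1 diabetes, and (with-CVD stratum only) the category of prior CVD with MI
alone as reference. Time-updated: current age (centred 60, per 10 years) and
duration since each first event as categories — no event / same year / 1 year
ago / 2 years ago / >= 3 years ago for MI, stroke and CRV; < 10 / >= 10 years
since diagnosis for diabetes; a finer scale up to >= 10 years for cancer —
plus same-year death indicators (vascular, non-vascular) and interactions for
co-occurring events (e.g. MI with same-year CRV). Categories that the original
selection merged share the preceding category's coefficient; the fixtures mark
them `merged_with_preceding` and the loader resolves them, so the engine never
needs special cases downstream.

## Encoding and numerical choices

- **Reference row.** For the reference individual with no events every
  non-intercept design entry is zero, with one documented exception: the
  stated reference creatinine of 81.5 umol/L is a rounding of
  `exp(4.4) = 81.45`, so the ln-creatinine entry is ~0.003 rather than 0 in
  the hospital models that retain creatinine. Predictions therefore differ
  from the intercept-only values by well under 0.1%; tests assert this bound
  rather than exact zero.
- **Rounded odds ratios.** Part-1 coefficients are encoded exactly as printed
  (two decimals) and used as `ln(OR)` sums for numerical stability. No attempt
  is made to back-solve unrounded values; the consequence, verified in the
  acceptance tests, is that two-part reference predictions agree with the
  published reference costs (244 and 376 GBP) to about 1%, not exactly.
- **Negative linear predictors.** The identity link admits negative predicted
  costs for extreme covariate combinations. Costs are non-negative by
  definition, so predictions are floored at 0 and flagged
  (`negative_linear_predictor_floored`); the flag is preserved through the CSV
  interfaces.
- **Missing categories.** Physical activity has a modelled "missing" level
  with printed coefficients and is treated as an ordinary category. Ethnicity
  "missing" has no printed coefficient; it maps to the reference level (white)
  at prediction time with a warning. Deprivation, smoking, diet and BMI have
  no missing levels in the profile schema; the simulator folds the cohort
  table's small "missing" shares into the reference categories.
- **Diabetes and cancer clocks.** The tables list a baseline type 1 diabetes
  term plus time-updated diabetes-duration categories. Baseline diabetes
  (either type) therefore enters through the duration covariate, clocked from
  years-since-diagnosis at entry and advanced annually; type 1 additionally
  activates its own term. Prior cancer seeds the cancer-duration clock the
  same way. Whether the original analysis clocked baseline disease from
  diagnosis or entry is a supplement-only detail; diagnosis date is the
  self-consistent choice with the time-updated definition.
- **Interaction semantics.** Interactions fire automatically whenever both
  component states hold in the same annual period, exactly as row-labelled:
  the primary care models pair "any incident MI/stroke" (any duration
  category) with same-year CRV/VD, the hospital models pair same-year with
  same-year. Users cannot toggle interactions independently, and a
  counterfactual that removes an event also removes its interactions.
- **Censoring covariate.** The original models adjusted administratively
  censored years with an unpublished proportion-of-year-unobserved covariate.
  The schema carries `observed_fraction`, but published fixtures attach no
  coefficient to it; predictions assume a fully observed year, including the
  year of death.
- **Rounding.** Published excess costs are rounded to 10 GBP; `round_to_ten()`
  rounds half away from zero, matching the printed values (e.g. -95 to -100).

## Excess costs by recycled prediction

The excess cost of an event at a timing category is the population mean of
each member's predicted cost with the event set to that timing minus the
prediction with the event absent, all else equal. For the linear primary care
model this difference is the sum of the active coefficients — identical for
every member, so the published primary care excess column is reproduced
exactly, for any population. For the two-part hospital model the difference
depends on each member's baseline odds, so population-average hospital
excesses depend on the population composition. The original hospital column
averages over the access-restricted source cohort and is *not* desk
reproducible; the package instead verifies the hospital machinery against an
independent brute-force evaluation of the two printed formulas on a degenerate
reference population, and checks the qualitative finding that same-year
co-occurrences (MI+CRV, MI+VD, stroke+VD) cost less than the sum of the
separate excesses (negative interaction coefficients).

Confidence intervals use the percentile bootstrap with participant-level
resampling (a participant's annual periods move together), 1000 resamples by
default. The original work says only "bootstrap approach"; percentile is the
simplest defensible reading and is what the width-coverage test verifies.

## The simulator: what it emulates, what it does not

The simulator exists so the estimation pipeline can be exercised end to end
with data whose generating process is known exactly.

- **Baseline covariates** are drawn independently from the cohort-description
  marginals (hospital-analysis columns): categorical proportions as printed,
  biomarkers as truncated normals with the printed means/SDs. Ages are
  truncated to the recruitment window 40-70. Years since baseline
  diabetes/cancer diagnosis are not printed; they default to Uniform(0, 20)
  and Uniform(0, 15) years respectively — wide, flat choices consistent with
  adult-onset disease ranges.
- **Events** fire per annual period with constant per-year hazards, first
  occurrences only, death absorbing (vascular and non-vascular death mutually
  exclusive within a year, resolved by a single categorical draw). Default
  hazards (MI 0.002, stroke 0.0017, CRV 0.0026, diabetes 0.003, cancer 0.0097,
  VD 0.00085, NVD 0.0033 per year) reproduce the source cohort's cumulative
  incidences over its 7.1-year average follow-up (MI 1.4%, stroke 1.2%, CRV
  1.8%, diabetes 2.1%, cancer 6.7%, VD 0.6%, NVD 2.3%). Co-occurrence
  parameters (same-year CRV probability 0.3 given incident MI; +0.05 same-year
  vascular-death risk after MI or stroke; +0.05 non-vascular-death risk with
  same-year cancer) are clinically motivated defaults that make the
  interaction terms identifiable in simulated panels; the source reports no
  co-occurrence rates, so these are stated once here and not tuned.
- **Costs** are generated from the published predictors: primary care costs
  from a positive noise family (default gamma, shape 1) with mean equal to the
  one-part linear predictor; hospital costs as Bernoulli(part-1 probability,
  respecting the CRV certainty rule) times a conditional draw (default gamma,
  shape 0.8) with mean from part 2. Gamma noise matches the right skew of real
  cost data; the shapes control dispersion only, since quasi-likelihood point
  estimation is consistent under a correct mean model regardless of the
  variance family. Non-positive generative means (possible under the identity
  link) are floored at 1 GBP.
- **Registration gaps**: a configurable fraction of person-years (default
  13.7%, the source's exclusion rate) is flagged `primary_excluded`; flagged
  rows never enter primary care fits but keep their hospital costs.
- **Admission allocation**: hospital stays spanning annual-period boundaries
  are split pro-rata by nights in each period, with a largest-remainder
  correction on pennies so the shares sum exactly; same-day admissions assign
  the whole cost to the period containing the admission date (a declared
  convention — nights are zero).

Not emulated: covariate correlation structure (all baseline fields are
independent), age-dependent hazards, within-year timing, outpatient care, and
real admission-level cost distributions. A green parameter-recovery test
therefore establishes that the estimator recovers the generative model from
data of the assumed form — not that the published models are correct for any
real population.

## The estimator

Fitting is iteratively reweighted least squares for quasi families defined by
their variance function (constant, mean, mean squared; binomial for part 1)
and link (identity, log; logit). Identity-link Poisson/Gamma fits step-halve
any update that would take a fitted mean non-positive (or the deviance up),
and report convergence status. Standard errors are one-way cluster-robust
sandwich estimates grouped by participant with a G/(G-1) small-sample factor;
with one observation per cluster this reduces to a heteroscedasticity-robust
estimator, verified against a delete-one jackknife.

Two-part fitting excludes same-year-CRV person-years from part 1 (cost there
is certain, mirroring the published certainty rule) and fits part 2 to the
cost-incurring rows. An all-positive panel flags part-1 separation and
degenerates to the one-part model.

The original specification-test battery is supplement-only, so the package
implements a documented stand-in: the modified Park test (regress log squared
residuals on log fitted means; slope near 0, 1, 2 points to
gaussian/poisson/gamma variance), AIC (exact for gaussian and binomial;
Pearson-scaled quasi-AIC otherwise), cross-validated RMSE/MAE and
predicted-observed correlation with folds split by participant, and
Hosmer-Lemeshow for the logistic part. Candidates are ranked by Park
consistency, ties broken by cross-validated RMSE, then identity link for
parsimony of interpretation.

Stepwise selection is bidirectional at a fixed level (published: 1%):
backward elimination drops the included block with the largest cluster-robust
Wald p-value at or above alpha; forward steps re-add the excluded block with
the smallest p-value below alpha; categorical covariates (and each event's
timing categories) move as blocks, so a selection can never keep some levels
of a covariate and drop others. Ties are broken by canonical term order and
revisited states terminate the search, making runs deterministic.

## Known limitations

- The published hospital-column excess averages and their CIs are functions of
  the unavailable source cohort; only their machinery is verifiable here.
- No coefficient covariance matrices are printed, so individual-level
  prediction intervals are out of scope unless the user supplies one.
- The models were estimated on 40-70 year olds followed to roughly age 80;
  extrapolation outside that range is unvalidated.
- The estimator's stand-in diagnostics are a reasonable reading of "common
  specification tests", not a reproduction of the original supplement.
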