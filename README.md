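# cvdcost

Individual-level prediction of annual UK healthcare costs associated with
cardiovascular and other major health events, in 2020 UK pounds.

Health-economic models of cardiovascular prevention (statins, blood-pressure
therapy, lifestyle policy) need the healthcare costs an individual incurs each
year, and how those costs jump when the person has a myocardial infarction
(MI), stroke, coronary revascularization (CRV), incident diabetes or cancer,
or dies of a vascular (VD) or non-vascular (NVD) cause. `cvdcost` implements a
published pair of UK cost-model families estimated on a large prospective
cohort with linked primary care and hospital admission records, separately for
people **without** and **with** previous cardiovascular disease (CVD):

- **Primary care costs** (consultations, tests, prescriptions): a one-part
  generalised linear model with Poisson variance and **identity link**, so
  every coefficient is an additive annual amount in pounds:

  `E[cost] = beta_0 + sum_i beta_i x_i`

- **Hospital inpatient costs**: a **two-part model**. Part 1 is a logistic
  regression for the probability of incurring any hospital cost in the year;
  part 2 is an identity-link Poisson GLM for the cost conditional on incurring
  any. Predicted annual cost:

  `Odds = exp( ln(odds_0) + sum_i ln(OR_i) x_i )`,
  `E[cost] = Odds/(1 + Odds) * ( gamma_0 + sum_i gamma_i x_i )`,

  with one certainty rule: in an annual period with same-year CRV, incurring
  hospital cost is certain (probability set to 1).

Covariates are baseline characteristics (sex, ethnicity, deprivation quintile,
smoking, physical activity, diet, BMI category, LDL/HDL cholesterol,
creatinine, blood pressure, antihypertensive treatment, severe mental illness,
prior type 1 diabetes, prior-CVD category) plus annually updated ones: current
age and duration-since-event categories (no event / same year / 1 / 2 / >= 3
years ago; diabetes < 10 / >= 10 years; cancer on a finer scale up to >= 10
years), with interactions for co-occurring same-year events. All published
coefficients ship as versioned JSON fixtures under `inst/extdata/` (one file
per stratum), including the temporal categories merged during the original
model selection.

The package also provides:

- **Excess costs by recycled prediction** (`recycled_excess()`,
  `excess_table()`): the population-mean difference between predictions with an
  event set to a timing category and with it absent, rounded to 10 GBP, with
  percentile bootstrap CIs (participant-level resampling).
- **A synthetic cohort simulator** (`sample_baseline()`, `simulate_events()`,
  `simulate_costs()`): baseline covariates from the published cohort's marginal
  distributions, per-year first-occurrence event hazards with absorbing death,
  and costs drawn with means given by the published model formulas — so the
  estimation pipeline can be validated end to end without any restricted data.
- **An estimation pipeline** (`fit_glm()`, `fit_two_part()`,
  `compare_candidates()`, `stepwise_select()`): quasi-likelihood IRLS for six
  GLM family/link pairs with step-halving guards for identity links,
  participant-clustered sandwich standard errors, modified Park test and
  cross-validated diagnostics, and bidirectional stepwise selection at a fixed
  significance level with categorical covariates moving as blocks.

## Worked example

A 60-year-old woman with reference characteristics and no CVD history has an
MI in her third annual period (year index 2):

```r
library(cvdcost)
models <- load_published_models()
predict_trajectory(reference_profile(), list(mi = 2),
                   horizon_years = 5, models = models)
```

```
  year_index current_age primary_gbp hospital_probability hospital_conditional_gbp hospital_gbp
1          0          60       262.0                 0.12                   2102.0       241.81
2          1          61       267.7                 0.12                   2119.3       250.84
3          2          62       467.4                 0.87                   5190.6      4501.15
4          3          63       473.1                 0.20                   2823.9       568.38
5          4          64       478.8                 0.18                   2475.2       434.52
```

Before the MI she costs ~262 GBP/year in primary care (the model intercept;
the +5.7/year drift is the age coefficient, 57 GBP per 10 years) and ~242
GBP/year in expected hospital costs (probability 0.12 of incurring any, times
2102 GBP conditional). In the MI year the primary care cost rises by the MI
coefficient (+194, persisting in later years) and the hospital cost jumps to
~4500 GBP as the odds of admission rise ~47-fold; two years later the hospital
excess has largely decayed while the primary care excess remains.

Published population-average excess costs are reproduced by recycled
prediction (here the primary care column; means rounded to 10 GBP):

```r
tab <- excess_table(models, list(reference_profile()),
                    strata = "without_cvd", services = "primary")
subset(tab, timing == "same_year", c(event, timing, mean_gbp))
#   event    timing mean_gbp
#      MI same_year      190
#  stroke same_year      360
#     CRV same_year      390
#      VD same_year     -100
#     NVD same_year      390
```

## Command line

```sh
CVDCOST=$(Rscript -e 'cat(system.file("exec", "cvdcost", package = "cvdcost"))')
Rscript $CVDCOST predict --profiles people.csv --stratum without_cvd --horizon 10 --out pred.csv
Rscript $CVDCOST excess --bootstrap 1000 --seed 1 --out excess.csv
Rscript $CVDCOST simulate-fit --config sim.yaml --out-dir run1
```

Configs are YAML (or JSON); outputs are comma/UTF-8/ISO-date CSV with a `#`
provenance header (package version, fixture checksums, seed, timestamp).

## Limitations

Hospital-column population averages of the published excess-cost table are
averages over the original (access-restricted) cohort and are not exactly
reproducible here; primary care excesses are exact because that model is
linear. Part-1 odds ratios are encoded as printed (2 decimal places), so
two-part reference predictions match the published ones to within ~1%.
Prediction intervals require a coefficient covariance matrix, which the tables
do not print. See `vignettes/cost-models.Rmd` for the full methods account.
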