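# Cohort sampling, event simulation, generative costs, admission allocation.

test_that("sample_baseline matches the stated marginals within Monte Carlo error", {
  n <- 50000
  co <- sample_baseline(n, "without_cvd", seed = 2024)
  mc3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex == "male") - 0.439), mc3(0.439))
  expect_lt(abs(mean(co$ldl_mmol_per_l) - 3.6), 3 * 0.8 / sqrt(n) + 0.01)
  expect_lt(abs(mean(co$smoking == "current") - 0.103), mc3(0.103))
  expect_lt(abs(mean(co$physical_activity == "missing") - 0.196), mc3(0.196))
  expect_true(all(co$prior_cvd_category == "none"))
  expect_true(all(co$hdl_mmol_per_l > 0))
  wi <- sample_baseline(5000, "with_cvd", seed = 11)
  expect_true(all(wi$prior_cvd_category != "none"))
  expect_lt(abs(mean(wi$prior_cvd_category == "other_chd_only") - 0.506),
            3 * sqrt(0.506 * 0.494 / 5000))
})

test_that("a single sampled profile is valid for its stratum", {
  co <- sample_baseline(1, "without_cvd", seed = 5)
  p <- cohort_profile(co, 1)
  expect_s3_class(p, "covariate_profile")
  expect_type(validate_profile(p, "without_cvd"), "character")
  expect_identical(sample_baseline(1, "without_cvd", seed = 5), co)  # determinism
})

test_that("simulate_events honours hazards and absorbing death", {
  co <- sample_baseline(2000, "without_cvd", seed = 1)
  zero <- simulation_config(n_participants = 2000, horizon_years = 5,
                            hazards = list(mi = 0, stroke = 0, crv = 0,
                                           diabetes = 0, cancer = 0, vd = 0,
                                           nvd = 0),
                            seed = 1)
  ev <- simulate_events(co, zero)
  expect_true(all(is.na(ev$mi_year)))
  expect_true(all(ev$n_years == 5))

  certain_death <- simulation_config(n_participants = 2000, horizon_years = 5,
                                     hazards = list(mi = 0, stroke = 0, crv = 0,
                                                    diabetes = 0, cancer = 0,
                                                    vd = 1, nvd = 0),
                                     seed = 1)
  ev2 <- simulate_events(co, certain_death)
  expect_true(all(ev2$vd_year == 0))
  expect_true(all(ev2$n_years == 1))

  # calibration: hazard 0.002/year, 7 years, no deaths -> closed-form incidence
  n <- 50000
  co3 <- sample_baseline(n, "without_cvd", seed = 3)
  cal <- simulation_config(n_participants = n, horizon_years = 7,
                           hazards = list(mi = 0.002, stroke = 0, crv = 0,
                                          diabetes = 0, cancer = 0, vd = 0,
                                          nvd = 0),
                           co_occurrence = list(),
                           seed = 3)
  ev3 <- simulate_events(co3, cal)
  p_true <- 1 - (1 - 0.002)^7
  expect_lt(abs(mean(!is.na(ev3$mi_year)) - p_true),
            3 * sqrt(p_true * (1 - p_true) / n))
  # determinism
  ev3b <- simulate_events(co3, cal)
  expect_identical(ev3, ev3b)
})

test_that("simulated costs have the model-implied means", {
  m <- models_all()
  n <- 30000
  cohort <- constant_cohort(reference_profile(), n)
  cfg <- simulation_config(n_participants = n, horizon_years = 1,
                           hazards = list(mi = 0, stroke = 0, crv = 0,
                                          diabetes = 0, cancer = 0, vd = 0,
                                          nvd = 0),
                           seed = 8)
  ev <- simulate_events(cohort, cfg)
  panel <- simulate_costs(cohort, ev, m, cfg)
  expect_identical(nrow(panel), as.integer(n))
  # reference primary mean 262, gamma shape 1 -> sd = 262
  expect_lt(abs(mean(panel$primary_gbp) - 262), 3 * 262 / sqrt(n))
  # any-cost fraction = 0.13/1.13 (up to the creatinine rounding ~81.5 vs e^4.4)
  p_ref <- panel$hospital_probability[1]
  expect_equal(p_ref, 0.13 / 1.13, tolerance = 1e-3)
  expect_lt(abs(mean(panel$hospital_any) - p_ref),
            3 * sqrt(p_ref * (1 - p_ref) / n))
  # conditional mean 2102 among cost-incurring person-years
  pos <- panel$hospital_any == 1
  expect_lt(abs(mean(panel$hospital_gbp[pos]) - 2102),
            3 * (2102 / sqrt(0.8)) / sqrt(sum(pos)))
  # determinism: same config -> bit-identical panel
  panel2 <- simulate_costs(cohort, ev, m, cfg)
  expect_identical(panel, panel2)
})

test_that("dispersion -> 0 concentrates simulated costs at the predicted means", {
  m <- models_all()
  n <- 200
  cohort <- constant_cohort(reference_profile(), n)
  cfg <- simulation_config(n_participants = n, horizon_years = 1,
                           hazards = list(mi = 0, stroke = 0, crv = 0,
                                          diabetes = 0, cancer = 0, vd = 0, nvd = 0),
                           primary_noise = list(family = "gamma", shape = 1e6),
                           seed = 9)
  ev <- simulate_events(cohort, cfg)
  panel <- simulate_costs(cohort, ev, m, cfg)
  expect_lt(max(abs(panel$primary_gbp - 262)), 262 * 0.01)
})

test_that("event states in simulated panels are internally consistent", {
  m <- models_all()
  cfg <- simulation_config(n_participants = 1500, horizon_years = 6,
                           hazards = list(mi = 0.03, stroke = 0.03, crv = 0.03,
                                          diabetes = 0.03, cancer = 0.03,
                                          vd = 0.01, nvd = 0.01),
                           seed = 10)
  panel <- suppressWarnings(simulate_panel(m, cfg))
  # death absorbs: no person-year after a death year
  dead <- panel[panel$vd == "yes" | panel$nvd == "yes", ]
  for (i in seq_len(nrow(dead))) {
    later <- panel$person_id == dead$person_id[i] &
      panel$year_index > dead$year_index[i]
    expect_identical(sum(later), 0L)
  }
  # monotone progression of duration categories for each person
  ord <- c(none = 0, same_year = 1, one_year_ago = 2, two_years_ago = 3,
           three_plus_years_ago = 4)
  by_person <- split(panel$mi, panel$person_id)
  steps <- unlist(lapply(by_person, function(v) diff(ord[v])))
  expect_true(all(steps >= 0))
  expect_true(all(steps <= 1))
  # at most one death indicator per person-year
  expect_identical(sum(panel$vd == "yes" & panel$nvd == "yes"), 0L)
})

test_that("allocate_admission_cost splits pro-rata and conserves the total", {
  b <- as.Date(c("2020-01-01", "2021-01-01", "2022-01-01"))
  # 10 nights: 3 in period 1 (Dec 29, 30, 31), 7 in period 2
  sh <- allocate_admission_cost(
    list(admission_date = "2020-12-29", discharge_date = "2021-01-08",
         total_cost_gbp = 1000),
    c(as.Date("2020-01-01"), as.Date("2021-01-01"), as.Date("2022-01-01")))
  expect_equal(unname(sh), c(300, 700))
  expect_identical(sum(sh), 1000)
  # stay within one period
  sh2 <- allocate_admission_cost(
    list(admission_date = "2020-03-01", discharge_date = "2020-03-11",
         total_cost_gbp = 500), b)
  expect_equal(unname(sh2), 500)
  # same-day admission: full cost to the containing period
  sh3 <- allocate_admission_cost(
    list(admission_date = "2021-06-01", discharge_date = "2021-06-01",
         total_cost_gbp = 199.99), b)
  expect_identical(names(sh3), "2021-01-01")
  expect_equal(unname(sh3), 199.99)
  expect_error(allocate_admission_cost(
    list(admission_date = "2019-06-01", discharge_date = "2019-06-01",
         total_cost_gbp = 10), b), "outside")
  expect_error(allocate_admission_cost(
    list(admission_date = "2020-03-02", discharge_date = "2020-03-01",
         total_cost_gbp = 10), b), "precedes")

  # conservation on random admissions spanning 1-3 annual periods
  set.seed(77)
  boundaries <- as.Date("2018-04-01") + 365 * 0:4
  for (i in 1:300) {
    adm <- as.Date("2018-04-01") + sample(0:1000, 1)
    stay <- sample(0:400, 1)
    cost <- round(runif(1, 0, 20000), 2)
    sh <- allocate_admission_cost(
      list(admission_date = adm,
           discharge_date = min(adm + stay, as.Date("2022-03-30")),
           total_cost_gbp = cost),
      boundaries)
    expect_equal(sum(sh), cost, tolerance = 1e-9)
    expect_true(all(sh >= 0))
  }
})

test_that("registration gaps mark the configured fraction of person-years", {
  m <- models_all()
  cfg <- simulation_config(n_participants = 4000, horizon_years = 4,
                           registration_gap_probability = 0.137, seed = 4)
  panel <- suppressWarnings(simulate_panel(m, cfg))
  p0 <- apply_registration_gaps(panel,
                                simulation_config(registration_gap_probability = 0))
  expect_true(all(!p0$primary_excluded))
  pg <- apply_registration_gaps(panel, cfg)
  n <- nrow(pg)
  expect_lt(abs(mean(pg$primary_excluded) - 0.137),
            3 * sqrt(0.137 * 0.863 / n))
  # hospital columns untouched
  expect_identical(pg$hospital_gbp, panel$hospital_gbp)
  # excluded rows never enter primary-care fitting
  fit <- fit_glm(pg, "primary_gbp", "poisson", "identity",
                 terms = list(term_intercept(),
                              term_level("male", "sex", "male")))
  expect_identical(fit$n_obs, sum(!pg$primary_excluded))
})
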