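# Design-row encoding and the one-part / two-part prediction formulas.

test_that("duration_category maps first-occurrence years to model categories", {
  expect_identical(duration_category(3, 3, "MI"), "same_year")
  expect_identical(duration_category(0, 7, "MI"), "three_plus_years_ago")
  expect_identical(duration_category(NA, 5, "stroke"), "none")
  expect_identical(duration_category(2, 3, "CRV"), "one_year_ago")
  expect_identical(duration_category(2, 4, "CRV"), "two_years_ago")
  expect_identical(duration_category(0, 9, "diabetes"), "lt10y")
  expect_identical(duration_category(0, 10, "diabetes"), "ge10y")
  expect_identical(duration_category(0, 0, "cancer"), "same_year")
  expect_identical(duration_category(0, 4, "cancer"), "four_years_ago")
  expect_identical(duration_category(0, 5, "cancer"), "five_to_ten")
  expect_identical(duration_category(0, 9, "cancer"), "five_to_ten")
  expect_identical(duration_category(0, 10, "cancer"), "ten_plus")
  expect_error(duration_category(5, 3, "MI"), "must not exceed")
})

test_that("reference profile encodes to an all-zero design row (intercept aside)", {
  m <- models_all()
  ref <- reference_profile()
  st <- annual_event_state()
  for (key in c("without_cvd.primary", "without_cvd.hospital_part1",
                "without_cvd.hospital_part2")) {
    row <- encode_design_row(ref, st, m[[key]])
    expect_identical(unname(row[1]), 1)
    # creatinine terms are not exactly 0: the stated reference creatinine of
    # 81.5 umol/L is a rounding of exp(4.4) = 81.45
    expect_lt(max(abs(row[-1])), 0.005)
    non_creat <- setdiff(names(row)[-1], "ln_creatinine")
    expect_identical(max(abs(row[non_creat])), 0)
  }
})

test_that("encoding applies the declared transforms and indicators", {
  m <- models_all()
  pm <- m[["without_cvd.primary"]]
  p <- covariate_profile(sex = "male", hdl_mmol_per_l = 1,
                         age_at_entry_years = 70)
  st <- event_state(p, year_index = 0)   # current age = 70
  row <- encode_design_row(p, st, pm)
  expect_identical(unname(row["male"]), 1)
  expect_identical(unname(row["age"]), 1)      # (70 - 60) / 10
  expect_identical(unname(row["ln_hdl"]), 0)   # ln 1 = 0
  p2 <- covariate_profile(ldl_mmol_per_l = 5.6, hdl_mmol_per_l = exp(1))
  row2 <- encode_design_row(p2, annual_event_state(), pm)
  expect_equal(unname(row2["ldl"]), 2)
  expect_equal(unname(row2["ln_hdl"]), 1)
  # interaction fires only when both components hold
  st_mi <- annual_event_state(mi = "two_years_ago", crv = "same_year")
  row3 <- encode_design_row(reference_profile(), st_mi, pm)
  expect_identical(unname(row3["mi_any_x_crv_same_year"]), 1)
  st_mi2 <- annual_event_state(mi = "two_years_ago", crv = "one_year_ago")
  row4 <- encode_design_row(reference_profile(), st_mi2, pm)
  expect_identical(unname(row4["mi_any_x_crv_same_year"]), 0)
})

test_that("reference predictions reproduce the published values", {
  m <- models_all()
  ref <- reference_profile()
  st <- annual_event_state()
  pm <- m[["without_cvd.primary"]]
  expect_equal(as.numeric(predict_primary_cost(encode_design_row(ref, st, pm), pm)),
               262)
  # adding the male indicator shifts the cost by the printed coefficient
  male <- covariate_profile(sex = "male")
  expect_equal(as.numeric(predict_primary_cost(encode_design_row(male, st, pm), pm)),
               262 - 51)
  refw <- reference_profile("with_cvd")
  pmw <- m[["with_cvd.primary"]]
  expect_equal(as.numeric(predict_primary_cost(encode_design_row(refw, st, pmw), pmw)),
               302)
  # two-part evaluation of the printed formula on printed coefficients
  # the printed reference creatinine (81.5) is a rounding of exp(4.4), so the
  # part-1 creatinine term contributes ~0.98^0.003 rather than exactly 1
  pr <- predict_costs(ref, st, m)
  expect_equal(pr$hospital_probability, 0.13 / 1.13, tolerance = 1e-4)
  expect_equal(pr$hospital_conditional_gbp, 2102)
  expect_equal(pr$hospital_gbp, 0.13 / 1.13 * 2102, tolerance = 1e-4)
  # paper's unrounded-coefficient values within rounding error (2%)
  expect_lt(abs(pr$hospital_gbp - 244) / 244, 0.02)
  prw <- predict_costs(refw, st, m)
  expect_lt(abs(prw$hospital_gbp - 376) / 376, 0.02)
})

test_that("same-year CRV makes incurring hospital cost certain", {
  m <- models_all()
  pr <- predict_costs(reference_profile(), annual_event_state(crv = "same_year"), m)
  expect_identical(pr$hospital_probability, 1)
  expect_identical(pr$hospital_gbp, pr$hospital_conditional_gbp)
  expect_true("certainty_rule_applied" %in% pr$flags)
})

test_that("negative linear predictors are floored at zero with a flag", {
  m <- models_all()
  pm <- m[["without_cvd.primary"]]
  # male, high HDL, VD year, MI+VD etc: build a state/profile pushing lp < 0
  p <- covariate_profile(sex = "male", hdl_mmol_per_l = 5,
                         ldl_mmol_per_l = 10, age_at_entry_years = 40)
  st <- annual_event_state(current_age_years = 40, vd_this_year = TRUE)
  row <- encode_design_row(p, st, pm)
  lp <- sum(vapply(pm$terms, `[[`, 0, "coefficient") * row)
  expect_lt(lp, 0)   # sanity: this configuration is genuinely negative
  pred <- predict_primary_cost(row, pm)
  expect_identical(as.numeric(pred), 0)
  expect_identical(attr(pred, "flags"), "negative_linear_predictor_floored")
})

test_that("predictions match the brute-force fixture oracle on random inputs", {
  m <- models_all()
  set.seed(42)
  n_bad <- 0
  for (i in 1:250) {
    stratum <- if (i %% 4 == 0) "with_cvd" else "without_cvd"
    p <- random_profile(stratum)
    st <- random_state(age = p$age_at_entry_years + sample(0:5, 1))
    vals <- model_frame_row(p, st)
    pr <- predict_costs(p, st, m, stratum)
    expect_equal(pr$primary_gbp, oracle_primary(vals, stratum),
                 tolerance = 1e-9)
    orc <- oracle_hospital(vals, stratum)
    expect_equal(pr$hospital_probability, orc$p, tolerance = 1e-9)
    expect_equal(pr$hospital_gbp, orc$total, tolerance = 1e-9)
  }
})

test_that("primary-model excess is the same linear shift for every profile", {
  m <- models_all()
  pm <- m[["without_cvd.primary"]]
  set.seed(7)
  st_off <- annual_event_state()
  st_on <- annual_event_state(mi = "same_year")
  diffs <- replicate(25, {
    p <- random_profile()
    on <- predict_primary_cost(encode_design_row(p, st_on, pm), pm)
    off <- predict_primary_cost(encode_design_row(p, st_off, pm), pm)
    as.numeric(on) - as.numeric(off)
  })
  expect_true(all(abs(diffs - 194) < 1e-9))
})

test_that("two-part predictions are bounded and odds are monotone", {
  m <- models_all()
  set.seed(11)
  for (i in 1:50) {
    p <- random_profile()
    st <- random_state(p$age_at_entry_years)
    pr <- predict_costs(p, st, m)
    expect_gte(pr$hospital_gbp, 0)
    expect_lte(pr$hospital_gbp, pr$hospital_conditional_gbp + 1e-12)
    expect_gte(pr$hospital_probability, 0)
    expect_lte(pr$hospital_probability, 1)
  }
  # adding a term with OR > 1 strictly increases the probability
  st0 <- annual_event_state()
  st1 <- annual_event_state(diabetes = "lt10y")    # OR 1.36
  p0 <- predict_costs(reference_profile(), st0, m)$hospital_probability
  p1 <- predict_costs(reference_profile(), st1, m)$hospital_probability
  expect_gt(p1, p0)
})

test_that("trajectories advance durations and stop at death", {
  m <- models_all()
  ref <- reference_profile()
  # MI at year 2, horizon 5: constant +194 primary excess from year 2 onward
  tr <- predict_trajectory(ref, list(mi = 2), 5, m)
  base <- predict_trajectory(ref, list(), 5, m)
  excess <- tr$primary_gbp - base$primary_gbp
  expect_equal(excess, c(0, 0, 194, 194, 194))
  # no events: hospital probability changes only through age drift
  expect_equal(nrow(base), 5)
  expect_true(all(diff(base$hospital_probability) > 0))
  # death is absorbing: VD at year 1 gives two annual periods
  tr_vd <- predict_trajectory(ref, list(vd = 1), 5, m)
  expect_identical(nrow(tr_vd), 2L)
  expect_error(predict_trajectory(ref, list(vd = 1, mi = 3), 5, m),
               "after the death year")
})
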