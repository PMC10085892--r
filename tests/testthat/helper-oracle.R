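# Independent brute-force evaluator: recomputes predictions directly from the
# raw fixture JSON (jsonlite), bypassing the package's coefficient_set /
# design-row machinery entirely. Used as the oracle for equivalence tests.

`%o||%` <- function(a, b) if (is.null(a)) b else a

oracle_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      docs <- lapply(cvdcost::published_model_paths(), jsonlite::read_json)
      out <- list()
      for (d in docs) for (m in d$models)
        out[[paste(m$stratum, m$service, sep = ".")]] <- m
      cache <<- out
    }
    cache
  }
})

# Printed estimate of term i, resolving merged categories by scanning back for
# the nearest non-merged term of the same event.
oracle_estimate <- function(terms, i) {
  t <- terms[[i]]
  if (!isTRUE(t$merged_with_preceding)) return(t$estimate)
  for (j in rev(seq_len(i - 1))) {
    p <- terms[[j]]
    if (identical(p$event, t$event) && !isTRUE(p$merged_with_preceding))
      return(p$estimate)
  }
  stop("no preceding category for merged term ", t$name)
}

oracle_term_value <- function(t, vals) {
  switch(t$kind,
    intercept = 1,
    categorical_level = as.numeric(vals[[t$field]] %in% unlist(t$levels)),
    continuous = {
      x <- as.numeric(vals[[t$field]])
      tr <- t$transform
      switch(tr$type,
        linear = (x - (tr$center %o||% 0)) / (tr$scale %o||% 1),
        log = log(x),
        log_linear = (log(x) - tr$center) / tr$scale)
    },
    interaction = {
      v <- 1
      for (cc in t$components)
        v <- v * as.numeric(vals[[cc$field]] %in% unlist(cc$levels))
      v
    })
}

# vals: canonical model-frame values (model_frame_row output).
oracle_linear_sum <- function(m, vals) {
  s <- 0
  for (i in seq_along(m$terms))
    s <- s + oracle_estimate(m$terms, i) * oracle_term_value(m$terms[[i]], vals)
  s
}

oracle_primary <- function(vals, stratum = "without_cvd") {
  m <- oracle_models()[[paste0(stratum, ".primary")]]
  max(0, oracle_linear_sum(m, vals))
}

oracle_hospital <- function(vals, stratum = "without_cvd") {
  m1 <- oracle_models()[[paste0(stratum, ".hospital_part1")]]
  m2 <- oracle_models()[[paste0(stratum, ".hospital_part2")]]
  odds <- 1
  for (i in seq_along(m1$terms))
    odds <- odds * oracle_estimate(m1$terms, i) ^
      oracle_term_value(m1$terms[[i]], vals)
  p <- odds / (1 + odds)
  if (identical(vals$crv, "same_year")) p <- 1    # table footnote d
  cond <- max(0, oracle_linear_sum(m2, vals))
  list(p = p, conditional = cond, total = p * cond)
}

# Random-but-valid profiles and event states for property tests.
random_profile <- function(stratum = "without_cvd") {
  covariate_profile(
    sex = sample(c("female", "male"), 1),
    ethnicity = sample(c("white", "black", "south_asian", "other"), 1),
    townsend_quintile = sample(paste0("q", 1:5), 1),
    smoking = sample(c("never", "former", "current"), 1),
    physical_activity = sample(c("low", "moderate", "high", "missing"), 1),
    diet = sample(c("healthy", "unhealthy"), 1),
    bmi_category = sample(c("lt18.5", "18.5to25", "25to30", "30to35",
                            "35to40", "ge40"), 1),
    ldl_mmol_per_l = runif(1, 1.5, 6),
    hdl_mmol_per_l = runif(1, 0.6, 2.5),
    creatinine_umol_per_l = runif(1, 40, 140),
    sbp_mmhg = runif(1, 100, 190),
    dbp_mmhg = runif(1, 60, 99),
    on_antihypertensive = runif(1) < 0.3,
    severe_mental_illness = runif(1) < 0.1,
    prior_type1_diabetes = runif(1) < 0.05,
    years_since_diabetes_diagnosis_at_entry = runif(1, 0, 20),
    prior_cvd_category = if (stratum == "with_cvd")
      sample(c("mi_only", "stroke_only", "pad_only", "other_chd_only",
               "two_or_more"), 1) else "none",
    age_at_entry_years = runif(1, 40, 70)
  )
}

random_state <- function(age = 60) {
  vd <- runif(1) < 0.1
  annual_event_state(
    year_index = sample(0:9, 1),
    current_age_years = age,
    mi = sample(c("none", "same_year", "one_year_ago", "two_years_ago",
                  "three_plus_years_ago"), 1, prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
    stroke = sample(c("none", "same_year", "one_year_ago", "two_years_ago",
                      "three_plus_years_ago"), 1, prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
    crv = sample(c("none", "same_year", "one_year_ago", "two_years_ago",
                   "three_plus_years_ago"), 1, prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
    diabetes = sample(c("none", "lt10y", "ge10y"), 1, prob = c(0.7, 0.2, 0.1)),
    cancer = sample(c("none", "same_year", "one_year_ago", "two_years_ago",
                      "three_years_ago", "four_years_ago", "five_to_ten",
                      "ten_plus"), 1,
                    prob = c(0.5, rep(0.5 / 7, 7))),
    vd_this_year = vd,
    nvd_this_year = !vd && runif(1) < 0.1
  )
}

# A cohort data.frame of n copies of a profile (sample_baseline schema).
constant_cohort <- function(profile, n, stratum = "without_cvd") {
  data.frame(
    person_id = seq_len(n), stratum = stratum,
    sex = profile$sex, ethnicity = profile$ethnicity,
    townsend_quintile = profile$townsend_quintile,
    smoking = profile$smoking,
    physical_activity = profile$physical_activity,
    diet = profile$diet, bmi_category = profile$bmi_category,
    ldl_mmol_per_l = profile$ldl_mmol_per_l,
    hdl_mmol_per_l = profile$hdl_mmol_per_l,
    creatinine_umol_per_l = profile$creatinine_umol_per_l,
    sbp_mmhg = profile$sbp_mmhg, dbp_mmhg = profile$dbp_mmhg,
    on_antihypertensive = profile$on_antihypertensive,
    severe_mental_illness = profile$severe_mental_illness,
    prior_type1_diabetes = profile$prior_type1_diabetes,
    prior_type2_diabetes = profile$prior_type2_diabetes,
    years_since_diabetes_diagnosis_at_entry =
      profile$years_since_diabetes_diagnosis_at_entry %o||% NA_real_,
    prior_cancer = profile$prior_cancer,
    years_since_cancer_diagnosis_at_entry =
      profile$years_since_cancer_diagnosis_at_entry %o||% NA_real_,
    prior_cvd_category = profile$prior_cvd_category,
    age_at_entry_years = profile$age_at_entry_years,
    stringsAsFactors = FALSE
  )
}

models_all <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_published_models()
    cache
  }
})
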