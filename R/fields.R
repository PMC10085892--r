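# Canonical model-frame fields shared by the coefficient fixtures, the design
# encoder, the simulator panel and the estimator. Every categorical field has a
# fixed level universe; the first level is the reference used by the published
# models.

.categorical_fields <- list(
  sex                   = c("female", "male"),
  ethnicity             = c("white", "black", "south_asian", "other", "missing"),
  townsend              = c("q3", "q1", "q2", "q4", "q5"),
  smoking               = c("never", "former", "current"),
  physical_activity     = c("moderate", "low", "high", "missing"),
  diet                  = c("healthy", "unhealthy"),
  bmi                   = c("18.5to25", "lt18.5", "25to30", "30to35", "35to40", "ge40"),
  antihypertensive      = c("no", "yes"),
  severe_mental_illness = c("no", "yes"),
  prior_type1_diabetes  = c("no", "yes"),
  prior_cvd             = c("none", "mi_only", "stroke_only", "pad_only",
                            "other_chd_only", "two_or_more"),
  mi                    = c("none", "same_year", "one_year_ago", "two_years_ago",
                            "three_plus_years_ago"),
  stroke                = c("none", "same_year", "one_year_ago", "two_years_ago",
                            "three_plus_years_ago"),
  crv                   = c("none", "same_year", "one_year_ago", "two_years_ago",
                            "three_plus_years_ago"),
  diabetes              = c("none", "lt10y", "ge10y"),
  cancer                = c("none", "same_year", "one_year_ago", "two_years_ago",
                            "three_years_ago", "four_years_ago", "five_to_ten",
                            "ten_plus"),
  vd                    = c("no", "yes"),
  nvd                   = c("no", "yes")
)

.numeric_fields <- c("ldl", "hdl", "creatinine", "sbp", "dbp", "current_age",
                     "observed_fraction")

# Categorical values that carry no coefficient in any published model and fall
# back to the reference level at prediction time (with a warning).
.reference_fallback <- list(ethnicity = "missing")

#' Cohort strata
#'
#' The cost models are estimated separately for people without and with
#' previous cardiovascular disease at study entry.
#' @return Character vector of the two stratum labels.
#' @export
cohort_strata <- function() c("without_cvd", "with_cvd")

#' Construct a baseline covariate profile
#'
#' Holds a person's characteristics at study entry in model-ready semantic
#' form. The defaults describe the reference individual of the published
#' models: a 60-year-old white female in Townsend quintile 3, never smoker,
#' moderate physical activity, healthy diet, BMI 18.5-25 kg/m2, LDL 3.6 mmol/L,
#' HDL 1 mmol/L, creatinine 81.5 umol/L, SBP 140 mmHg, DBP 80 mmHg, untreated
#' and free of comorbidity.
#'
#' @param sex "female" or "male".
#' @param ethnicity one of "white", "black", "south_asian", "other", "missing".
#' @param townsend_quintile Townsend deprivation quintile, "q1".."q5"
#'   (q1 least deprived; q3 is the model reference).
#' @param smoking "never", "former" or "current".
#' @param physical_activity "low", "moderate", "high" or "missing"
#'   ("missing" is a modelled category with its own coefficient).
#' @param diet "healthy" or "unhealthy".
#' @param bmi_category one of "lt18.5", "18.5to25", "25to30", "30to35",
#'   "35to40", "ge40" (kg/m2).
#' @param ldl_mmol_per_l LDL cholesterol, mmol/L (non-negative).
#' @param hdl_mmol_per_l HDL cholesterol, mmol/L (strictly positive; its
#'   natural log enters the models).
#' @param creatinine_umol_per_l serum creatinine, umol/L (strictly positive).
#' @param sbp_mmhg systolic blood pressure, mmHg.
#' @param dbp_mmhg diastolic blood pressure, mmHg.
#' @param on_antihypertensive logical.
#' @param severe_mental_illness logical.
#' @param prior_type1_diabetes,prior_type2_diabetes logicals; baseline diabetes
#'   also feeds the time-updated diabetes-duration covariate through
#'   `years_since_diabetes_diagnosis_at_entry`.
#' @param years_since_diabetes_diagnosis_at_entry years since diabetes
#'   diagnosis at entry (required if either diabetes flag is set).
#' @param prior_cancer logical.
#' @param years_since_cancer_diagnosis_at_entry years since cancer diagnosis at
#'   entry (required if `prior_cancer`).
#' @param prior_cvd_category one of "none", "mi_only", "stroke_only",
#'   "pad_only", "other_chd_only", "two_or_more". Must be "none" exactly when
#'   the person belongs to the without-CVD stratum.
#' @param age_at_entry_years age at study entry, years (18-110).
#' @return An object of class `covariate_profile` (named list).
#' @export
covariate_profile <- function(sex = "female",
                              ethnicity = "white",
                              townsend_quintile = "q3",
                              smoking = "never",
                              physical_activity = "moderate",
                              diet = "healthy",
                              bmi_category = "18.5to25",
                              ldl_mmol_per_l = 3.6,
                              hdl_mmol_per_l = 1,
                              creatinine_umol_per_l = 81.5,
                              sbp_mmhg = 140,
                              dbp_mmhg = 80,
                              on_antihypertensive = FALSE,
                              severe_mental_illness = FALSE,
                              prior_type1_diabetes = FALSE,
                              prior_type2_diabetes = FALSE,
                              years_since_diabetes_diagnosis_at_entry = NULL,
                              prior_cancer = FALSE,
                              years_since_cancer_diagnosis_at_entry = NULL,
                              prior_cvd_category = "none",
                              age_at_entry_years = 60) {
  p <- list(
    sex = match.arg(sex, .categorical_fields$sex),
    ethnicity = match.arg(ethnicity, .categorical_fields$ethnicity),
    townsend_quintile = match.arg(townsend_quintile, sort(.categorical_fields$townsend)),
    smoking = match.arg(smoking, .categorical_fields$smoking),
    physical_activity = match.arg(physical_activity, .categorical_fields$physical_activity),
    diet = match.arg(diet, .categorical_fields$diet),
    bmi_category = match.arg(bmi_category, .categorical_fields$bmi),
    ldl_mmol_per_l = as.numeric(ldl_mmol_per_l),
    hdl_mmol_per_l = as.numeric(hdl_mmol_per_l),
    creatinine_umol_per_l = as.numeric(creatinine_umol_per_l),
    sbp_mmhg = as.numeric(sbp_mmhg),
    dbp_mmhg = as.numeric(dbp_mmhg),
    on_antihypertensive = isTRUE(on_antihypertensive),
    severe_mental_illness = isTRUE(severe_mental_illness),
    prior_type1_diabetes = isTRUE(prior_type1_diabetes),
    prior_type2_diabetes = isTRUE(prior_type2_diabetes),
    years_since_diabetes_diagnosis_at_entry =
      if (is.null(years_since_diabetes_diagnosis_at_entry)) NULL
      else as.numeric(years_since_diabetes_diagnosis_at_entry),
    prior_cancer = isTRUE(prior_cancer),
    years_since_cancer_diagnosis_at_entry =
      if (is.null(years_since_cancer_diagnosis_at_entry)) NULL
      else as.numeric(years_since_cancer_diagnosis_at_entry),
    prior_cvd_category = match.arg(prior_cvd_category, .categorical_fields$prior_cvd),
    age_at_entry_years = as.numeric(age_at_entry_years)
  )
  if (p$hdl_mmol_per_l <= 0)
    stop("hdl_mmol_per_l must be strictly positive (its natural log is taken)")
  if (p$creatinine_umol_per_l <= 0)
    stop("creatinine_umol_per_l must be strictly positive")
  if (p$ldl_mmol_per_l < 0) stop("ldl_mmol_per_l must be non-negative")
  if (p$age_at_entry_years < 18 || p$age_at_entry_years > 110)
    stop("age_at_entry_years must lie in [18, 110]")
  if ((p$prior_type1_diabetes || p$prior_type2_diabetes) &&
      is.null(p$years_since_diabetes_diagnosis_at_entry))
    p$years_since_diabetes_diagnosis_at_entry <- 0
  if (p$prior_cancer && is.null(p$years_since_cancer_diagnosis_at_entry))
    p$years_since_cancer_diagnosis_at_entry <- 0
  structure(p, class = "covariate_profile")
}

#' The reference individual of the published models
#'
#' @param stratum "without_cvd" or "with_cvd". In the with-CVD stratum the
#'   reference history is prior MI alone.
#' @return A `covariate_profile`.
#' @export
reference_profile <- function(stratum = c("without_cvd", "with_cvd")) {
  stratum <- match.arg(stratum)
  covariate_profile(
    prior_cvd_category = if (stratum == "with_cvd") "mi_only" else "none"
  )
}

#' Construct a per-year event state
#'
#' Time-updated state for one annual period: current age, duration-since-event
#' category for each event, death indicators and the observed fraction of the
#' year.
#'
#' @param year_index non-negative integer; 0 is the first annual period after
#'   entry.
#' @param current_age_years current age in years.
#' @param mi,stroke,crv duration category, one of "none", "same_year",
#'   "one_year_ago", "two_years_ago", "three_plus_years_ago".
#' @param diabetes "none", "lt10y" or "ge10y".
#' @param cancer one of "none", "same_year", "one_year_ago", "two_years_ago",
#'   "three_years_ago", "four_years_ago", "five_to_ten", "ten_plus".
#' @param vd_this_year,nvd_this_year logicals; at most one may be TRUE
#'   (death is absorbing).
#' @param observed_fraction fraction of the annual period observed, in (0, 1].
#' @return An object of class `annual_event_state`.
#' @export
annual_event_state <- function(year_index = 0,
                               current_age_years = 60,
                               mi = "none", stroke = "none", crv = "none",
                               diabetes = "none", cancer = "none",
                               vd_this_year = FALSE, nvd_this_year = FALSE,
                               observed_fraction = 1) {
  s <- list(
    year_index = as.integer(year_index),
    current_age_years = as.numeric(current_age_years),
    mi = match.arg(mi, .categorical_fields$mi),
    stroke = match.arg(stroke, .categorical_fields$stroke),
    crv = match.arg(crv, .categorical_fields$crv),
    diabetes = match.arg(diabetes, .categorical_fields$diabetes),
    cancer = match.arg(cancer, .categorical_fields$cancer),
    vd_this_year = isTRUE(vd_this_year),
    nvd_this_year = isTRUE(nvd_this_year),
    observed_fraction = as.numeric(observed_fraction)
  )
  if (s$year_index < 0) stop("year_index must be non-negative")
  if (s$vd_this_year && s$nvd_this_year)
    stop("at most one of vd_this_year/nvd_this_year may be TRUE")
  if (s$observed_fraction <= 0 || s$observed_fraction > 1)
    stop("observed_fraction must lie in (0, 1]")
  structure(s, class = "annual_event_state")
}

#' Duration-since-event category
#'
#' Maps a first-occurrence year to the event-specific temporal category used
#' by the models: MI, stroke and CRV use no event / same year / 1 year ago /
#' 2 years ago / >= 3 years ago; diabetes uses < 10 / >= 10 years since
#' diagnosis; cancer uses same year / 1 / 2 / 3 / 4 years ago / 5 to < 10 /
#' >= 10 years ago.
#'
#' @param event_first_year integer year index of the first occurrence, or `NA`
#'   / `NULL` for no event.
#' @param current_year integer year index of the annual period being encoded.
#' @param event_kind one of "MI", "stroke", "CRV", "diabetes", "cancer".
#' @return The category label (character scalar).
#' @export
duration_category <- function(event_first_year, current_year,
                              event_kind = c("MI", "stroke", "CRV",
                                             "diabetes", "cancer")) {
  event_kind <- match.arg(event_kind)
  if (is.null(event_first_year) || is.na(event_first_year)) return("none")
  if (event_first_year > current_year)
    stop("event_first_year must not exceed current_year")
  d <- current_year - event_first_year
  switch(event_kind,
    MI = , stroke = , CRV = {
      if (d == 0) "same_year"
      else if (d == 1) "one_year_ago"
      else if (d == 2) "two_years_ago"
      else "three_plus_years_ago"
    },
    diabetes = if (d < 10) "lt10y" else "ge10y",
    cancer = {
      if (d == 0) "same_year"
      else if (d <= 4) c("one_year_ago", "two_years_ago", "three_years_ago",
                         "four_years_ago")[d]
      else if (d < 10) "five_to_ten"
      else "ten_plus"
    }
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive the event state for one annual period
#'
#' Advances age and duration categories from a profile plus a map of
#' first-occurrence years. Baseline (prior) diabetes and cancer seed the
#' corresponding duration clocks using the years-since-diagnosis fields; an
#' incident event during follow-up starts its clock at the event year.
#'
#' @param profile a `covariate_profile`.
#' @param event_first_years named list/vector of first-occurrence year indices
#'   with any of the names mi, stroke, crv, diabetes, cancer, vd, nvd
#'   (NA or absent = no event).
#' @param year_index the annual period to describe.
#' @param observed_fraction observed fraction of the year.
#' @return An `annual_event_state`.
#' @export
event_state <- function(profile, event_first_years = list(), year_index = 0,
                        observed_fraction = 1) {
  ev <- function(nm) {
    y <- event_first_years[[nm]]
    # events that have not occurred by this annual period count as absent
    if (is.null(y) || is.na(y) || y > year_index) NA_integer_ else as.integer(y)
  }
  dia_first <- ev("diabetes")
  dia <- if (profile$prior_type1_diabetes || profile$prior_type2_diabetes) {
    since <- profile$years_since_diabetes_diagnosis_at_entry + year_index
    if (since < 10) "lt10y" else "ge10y"
  } else duration_category(dia_first, year_index, "diabetes")
  can_first <- ev("cancer")
  can <- if (profile$prior_cancer) {
    eff_first <- -floor(profile$years_since_cancer_diagnosis_at_entry)
    duration_category(min(eff_first, can_first, na.rm = TRUE), year_index, "cancer")
  } else duration_category(can_first, year_index, "cancer")
  annual_event_state(
    year_index = year_index,
    current_age_years = profile$age_at_entry_years + year_index,
    mi = duration_category(ev("mi"), year_index, "MI"),
    stroke = duration_category(ev("stroke"), year_index, "stroke"),
    crv = duration_category(ev("crv"), year_index, "CRV"),
    diabetes = dia, cancer = can,
    vd_this_year = !is.na(ev("vd")) && ev("vd") == year_index,
    nvd_this_year = !is.na(ev("nvd")) && ev("nvd") == year_index,
    observed_fraction = observed_fraction
  )
}

#' Flatten a (profile, state) pair into the canonical model frame row
#'
#' The model frame is the flat named representation the coefficient fixtures
#' refer to: categorical fields as level strings, numerics untransformed.
#'
#' @param profile a `covariate_profile`.
#' @param state an `annual_event_state`.
#' @return Named list of field values.
#' @export
model_frame_row <- function(profile, state) {
  list(
    sex = profile$sex,
    ethnicity = profile$ethnicity,
    townsend = profile$townsend_quintile,
    smoking = profile$smoking,
    physical_activity = profile$physical_activity,
    diet = profile$diet,
    bmi = profile$bmi_category,
    ldl = profile$ldl_mmol_per_l,
    hdl = profile$hdl_mmol_per_l,
    creatinine = profile$creatinine_umol_per_l,
    sbp = profile$sbp_mmhg,
    dbp = profile$dbp_mmhg,
    antihypertensive = if (profile$on_antihypertensive) "yes" else "no",
    severe_mental_illness = if (profile$severe_mental_illness) "yes" else "no",
    prior_type1_diabetes = if (profile$prior_type1_diabetes) "yes" else "no",
    prior_cvd = profile$prior_cvd_category,
    current_age = state$current_age_years,
    mi = state$mi, stroke = state$stroke, crv = state$crv,
    diabetes = state$diabetes, cancer = state$cancer,
    vd = if (state$vd_this_year) "yes" else "no",
    nvd = if (state$nvd_this_year) "yes" else "no",
    observed_fraction = state$observed_fraction
  )
}

# Internal: check a frame value vector against the registry; unknown level is
# an error, fallback levels map to reference with a warning.
.check_frame_levels <- function(field, values) {
  universe <- .categorical_fields[[field]]
  if (is.null(universe)) return(values)
  bad <- setdiff(unique(values), universe)
  if (length(bad))
    stop(sprintf("unmapped category '%s' for field '%s'", bad[1], field))
  fb <- .reference_fallback[[field]]
  if (!is.null(fb) && any(values == fb)) {
    warning(sprintf(
      "field '%s' value '%s' has no model coefficient; mapped to reference level",
      field, fb))
    values[values == fb] <- universe[1]
  }
  values
}
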