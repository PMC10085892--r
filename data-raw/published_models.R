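# Builds inst/extdata/published_models_2020_<stratum>.json files, the structured-text encoding
# of the published coefficient tables (2020 UK pounds). Run from repo root:
#   Rscript data-raw/published_models.R

lvl <- function(name, label, field, levels, est, se = NULL,
                event = NULL, timing = NULL) {
  list(name = name, label = label, kind = "categorical_level",
       field = field, levels = as.list(levels),
       transform = NULL, components = NULL,
       event = event, timing = timing,
       estimate = est, se = se, merged_with_preceding = FALSE)
}
mrg <- function(name, label, field, levels, event = NULL, timing = NULL) {
  list(name = name, label = label, kind = "categorical_level",
       field = field, levels = as.list(levels),
       transform = NULL, components = NULL,
       event = event, timing = timing,
       estimate = NULL, se = NULL, merged_with_preceding = TRUE)
}
cont <- function(name, label, field, type, est, se = NULL,
                 center = NULL, scale = NULL) {
  tr <- list(type = type)
  if (!is.null(center)) tr$center <- center
  if (!is.null(scale)) tr$scale <- scale
  list(name = name, label = label, kind = "continuous",
       field = field, levels = NULL, transform = tr, components = NULL,
       event = NULL, timing = NULL,
       estimate = est, se = se, merged_with_preceding = FALSE)
}
inter <- function(name, label, comps, est, se = NULL) {
  list(name = name, label = label, kind = "interaction",
       field = NULL, levels = NULL, transform = NULL,
       components = lapply(comps, function(cc)
         list(field = cc[[1]], levels = as.list(cc[[2]]))),
       event = NULL, timing = NULL,
       estimate = est, se = se, merged_with_preceding = FALSE)
}
icpt <- function(est, se = NULL) {
  list(name = "intercept", label = "Intercept", kind = "intercept",
       field = NULL, levels = NULL, transform = NULL, components = NULL,
       event = NULL, timing = NULL,
       estimate = est, se = se, merged_with_preceding = FALSE)
}

ALL4 <- c("same_year", "one_year_ago", "two_years_ago", "three_plus_years_ago")
ONEPLUS <- c("one_year_ago", "two_years_ago", "three_plus_years_ago")
CAN_LT5 <- c("same_year", "one_year_ago", "two_years_ago", "three_years_ago",
             "four_years_ago")
CAN_5PLUS <- c("five_to_ten", "ten_plus")

## ---- Primary care, without previous CVD -----------------------------------
primary_wo <- list(
  icpt(262, 4),
  lvl("male", "Male", "sex", "male", -51, 3),
  lvl("ethnicity_black", "Black", "ethnicity", "black", -3, 11),
  lvl("ethnicity_south_asian", "South Asian", "ethnicity", "south_asian", 57, 9),
  lvl("ethnicity_other", "Other ethnicity", "ethnicity", "other", -3, 2),
  lvl("townsend_q1", "Townsend quintile 1", "townsend", "q1", -5, 1),
  lvl("townsend_q2", "Townsend quintile 2", "townsend", "q2", 4, 2),
  lvl("townsend_q4", "Townsend quintile 4", "townsend", "q4", 6, 3),
  lvl("townsend_q5", "Townsend quintile 5", "townsend", "q5", 50, 6),
  lvl("smoking_former", "Former smoker", "smoking", "former", 22, 2),
  lvl("smoking_current", "Current smoker", "smoking", "current", 50, 5),
  lvl("pa_low", "Low physical activity", "physical_activity", "low", 30, 5),
  lvl("pa_high", "High physical activity", "physical_activity", "high", -2, 2),
  lvl("pa_missing", "Missing physical activity", "physical_activity", "missing", 32, 4),
  lvl("bmi_lt18.5", "BMI < 18.5", "bmi", "lt18.5", 36, 15),
  lvl("bmi_25to30", "BMI 25-30", "bmi", "25to30", 3, 2),
  lvl("bmi_30to35", "BMI 30-35", "bmi", "30to35", 31, 4),
  lvl("bmi_35to40", "BMI 35-40", "bmi", "35to40", 91, 9),
  lvl("bmi_ge40", "BMI >= 40", "bmi", "ge40", 132, 13),
  cont("ldl", "LDL cholesterol (centred at 3.6; per 1 mmol/L)", "ldl",
       "linear", -6, 2, center = 3.6, scale = 1),
  cont("ln_hdl", "Natural logarithm of HDL cholesterol", "hdl", "log", -32, 6),
  lvl("antihypertensive", "On antihypertensive treatment",
      "antihypertensive", "yes", 127, 5),
  lvl("severe_mental_illness", "Severe mental illness history",
      "severe_mental_illness", "yes", 152, 6),
  lvl("prior_type1_diabetes", "Prior type 1 diabetes",
      "prior_type1_diabetes", "yes", 643, 45),
  cont("age", "Current age (centred at 60; per 10 years)", "current_age",
       "linear", 57, 2, center = 60, scale = 10),
  lvl("mi_any", "Incident MI", "mi", ALL4, 194, 24,
      event = "MI", timing = "any"),
  lvl("stroke_any", "Incident stroke", "stroke", ALL4, 362, 56,
      event = "stroke", timing = "any"),
  lvl("crv_same_year", "Incident CRV, same year", "crv", "same_year", 391, 40,
      event = "CRV", timing = "same_year"),
  lvl("crv_1plus", "Incident CRV, >= 1 year ago", "crv", ONEPLUS, 69, 15,
      event = "CRV", timing = "one_plus"),
  lvl("diabetes_lt10y", "Diabetes < 10 years ago", "diabetes", "lt10y", 360, 11,
      event = "diabetes", timing = "lt10y"),
  lvl("diabetes_ge10y", "Diabetes >= 10 years ago", "diabetes", "ge10y", 560, 19,
      event = "diabetes", timing = "ge10y"),
  lvl("cancer_lt5y", "Cancer < 5 years", "cancer", CAN_LT5, 357, 11,
      event = "cancer", timing = "lt5y"),
  lvl("cancer_5to10y", "Cancer >= 5, < 10 years", "cancer", "five_to_ten", 159, 13,
      event = "cancer", timing = "5to10y"),
  lvl("cancer_ge10y", "Cancer >= 10 years ago", "cancer", "ten_plus", 77, 6,
      event = "cancer", timing = "ge10y"),
  lvl("vd", "VD", "vd", "yes", -95, 30, event = "VD", timing = "same_year"),
  lvl("nvd", "NVD", "nvd", "yes", 389, 37, event = "NVD", timing = "same_year"),
  inter("mi_any_x_crv_same_year", "Any incident MI and same year CRV",
        list(list("mi", ALL4), list("crv", "same_year")), -226, 47),
  inter("stroke_any_x_vd", "Any incident stroke and same year VD",
        list(list("stroke", ALL4), list("vd", "yes")), -277, 86),
  inter("cancer_lt5y_x_nvd", "< 5 years cancer and same year NVD",
        list(list("cancer", CAN_LT5), list("nvd", "yes")), -245, 47)
)

## ---- Primary care, with previous CVD --------------------------------------
primary_wi <- list(
  icpt(302, 22),
  lvl("male", "Male", "sex", "male", -50, 13),
  lvl("ethnicity_black", "Black", "ethnicity", "black", 61, 127),
  lvl("ethnicity_south_asian", "South Asian", "ethnicity", "south_asian", 24, 36),
  lvl("ethnicity_other", "Other ethnicity", "ethnicity", "other", -107, 24),
  lvl("townsend_q1", "Townsend quintile 1", "townsend", "q1", 6, 17),
  lvl("townsend_q2", "Townsend quintile 2", "townsend", "q2", 25, 17),
  lvl("townsend_q4", "Townsend quintile 4", "townsend", "q4", 49, 21),
  lvl("townsend_q5", "Townsend quintile 5", "townsend", "q5", 132, 34),
  lvl("pa_low", "Low physical activity", "physical_activity", "low", 117, 21),
  lvl("pa_high", "High physical activity", "physical_activity", "high", -8, 10),
  lvl("pa_missing", "Missing physical activity", "physical_activity", "missing", 96, 21),
  lvl("bmi_lt18.5", "BMI < 18.5", "bmi", "lt18.5", 182, 107),
  lvl("bmi_25to30", "BMI 25-30", "bmi", "25to30", 8, 11),
  lvl("bmi_30to35", "BMI 30-35", "bmi", "30to35", 58, 16),
  lvl("bmi_35to40", "BMI 35-40", "bmi", "35to40", 194, 46),
  lvl("bmi_ge40", "BMI >= 40", "bmi", "ge40", 329, 44),
  cont("sbp", "Systolic blood pressure (centred at 140; per 20 mmHg)", "sbp",
       "linear", -20, 6, center = 140, scale = 20),
  lvl("antihypertensive", "On antihypertensive treatment",
      "antihypertensive", "yes", 93, 14),
  lvl("severe_mental_illness", "Severe mental illness history",
      "severe_mental_illness", "yes", 280, 31),
  lvl("prior_type1_diabetes", "Prior type 1 diabetes",
      "prior_type1_diabetes", "yes", 731, 78),
  lvl("prior_cvd_pad_only", "Prior CVD: PAD only", "prior_cvd", "pad_only", 66, 19),
  lvl("prior_cvd_stroke_only", "Prior CVD: stroke only", "prior_cvd",
      "stroke_only", 124, 37),
  lvl("prior_cvd_other_chd_only", "Prior CVD: other CHD only", "prior_cvd",
      "other_chd_only", 84, 17),
  lvl("prior_cvd_two_or_more", "Prior CVD: two or more", "prior_cvd",
      "two_or_more", 221, 22),
  cont("age", "Current age (centred at 60; per 10 years)", "current_age",
       "linear", 62, 7, center = 60, scale = 10),
  lvl("mi_any", "Incident MI", "mi", ALL4, 231, 54,
      event = "MI", timing = "any"),
  lvl("stroke_any", "Incident stroke", "stroke", ALL4, 428, 82,
      event = "stroke", timing = "any"),
  lvl("crv_same_year", "Incident CRV, same year", "crv", "same_year", 233, 33,
      event = "CRV", timing = "same_year"),
  lvl("crv_1plus", "Incident CRV, >= 1 year ago", "crv", ONEPLUS, 10, 26,
      event = "CRV", timing = "one_plus"),
  lvl("diabetes_lt10y", "Diabetes < 10 years ago", "diabetes", "lt10y", 343, 24,
      event = "diabetes", timing = "lt10y"),
  lvl("diabetes_ge10y", "Diabetes >= 10 years ago", "diabetes", "ge10y", 568, 39,
      event = "diabetes", timing = "ge10y"),
  lvl("cancer_lt5y", "Cancer < 5 years", "cancer", CAN_LT5, 236, 25,
      event = "cancer", timing = "lt5y"),
  lvl("cancer_5to10y", "Cancer >= 5, < 10 years", "cancer", "five_to_ten", 123, 28,
      event = "cancer", timing = "5to10y"),
  mrg("cancer_ge10y", "Cancer >= 10 years ago", "cancer", "ten_plus",
      event = "cancer", timing = "ge10y"),
  lvl("vd", "VD", "vd", "yes", -16, 91, event = "VD", timing = "same_year"),
  lvl("nvd", "NVD", "nvd", "yes", 198, 65, event = "NVD", timing = "same_year"),
  inter("mi_any_x_vd", "Any incident MI and same year VD",
        list(list("mi", ALL4), list("vd", "yes")), -500, 109),
  inter("stroke_any_x_vd", "Any incident stroke and same year VD",
        list(list("stroke", ALL4), list("vd", "yes")), -439, 133)
)

## ---- Hospital part 1 (logistic; estimates are odds / odds ratios) ---------
## without previous CVD
h1_wo <- list(
  icpt(0.13),
  lvl("male", "Male", "sex", "male", 0.92),
  lvl("ethnicity_black", "Black", "ethnicity", "black", 1.04),
  lvl("ethnicity_south_asian", "South Asian", "ethnicity", "south_asian", 1.14),
  lvl("ethnicity_other", "Other ethnicity", "ethnicity", "other", 1.03),
  lvl("townsend_q1", "Townsend quintile 1", "townsend", "q1", 0.95),
  lvl("townsend_q2", "Townsend quintile 2", "townsend", "q2", 0.99),
  lvl("townsend_q4", "Townsend quintile 4", "townsend", "q4", 1.07),
  lvl("townsend_q5", "Townsend quintile 5", "townsend", "q5", 1.17),
  lvl("smoking_former", "Former smoker", "smoking", "former", 1.11),
  lvl("smoking_current", "Current smoker", "smoking", "current", 1.2),
  lvl("pa_low", "Low physical activity", "physical_activity", "low", 1.1),
  lvl("pa_high", "High physical activity", "physical_activity", "high", 1.07),
  lvl("pa_missing", "Missing physical activity", "physical_activity", "missing", 1.14),
  lvl("diet_unhealthy", "Unhealthy diet", "diet", "unhealthy", 1.06),
  lvl("bmi_lt18.5", "BMI < 18.5", "bmi", "lt18.5", 1.13),
  lvl("bmi_25to30", "BMI 25-30", "bmi", "25to30", 1.12),
  lvl("bmi_30to35", "BMI 30-35", "bmi", "30to35", 1.24),
  lvl("bmi_35to40", "BMI 35-40", "bmi", "35to40", 1.36),
  lvl("bmi_ge40", "BMI >= 40", "bmi", "ge40", 1.51),
  cont("ldl", "LDL cholesterol (centred at 3.6; per 1 mmol/L)", "ldl",
       "linear", 0.97, center = 3.6, scale = 1),
  cont("ln_hdl", "Natural logarithm of HDL cholesterol", "hdl", "log", 0.86),
  cont("ln_creatinine",
       "Natural logarithm of creatinine (centred at 4.4; per 0.2 ln umol/L)",
       "creatinine", "log_linear", 0.98, center = 4.4, scale = 0.2),
  cont("sbp", "Systolic blood pressure (centred at 140; per 20 mmHg)", "sbp",
       "linear", 0.93, center = 140, scale = 20),
  cont("dbp", "Diastolic blood pressure (centred at 80; per 10 mmHg)", "dbp",
       "linear", 1.02, center = 80, scale = 10),
  lvl("antihypertensive", "On antihypertensive treatment",
      "antihypertensive", "yes", 1.14),
  lvl("severe_mental_illness", "Severe mental illness history",
      "severe_mental_illness", "yes", 1.43),
  lvl("prior_type1_diabetes", "Prior type 1 diabetes",
      "prior_type1_diabetes", "yes", 1.83),
  cont("age", "Current age (centred at 60; per 10 years)", "current_age",
       "linear", 1.38, center = 60, scale = 10),
  lvl("mi_same_year", "Incident MI, same year", "mi", "same_year", 47.09,
      event = "MI", timing = "same_year"),
  lvl("mi_1y", "Incident MI, 1 year ago", "mi", "one_year_ago", 1.76,
      event = "MI", timing = "one_year_ago"),
  lvl("mi_2y", "Incident MI, 2 years ago", "mi", "two_years_ago", 1.44,
      event = "MI", timing = "two_years_ago"),
  lvl("mi_3plus", "Incident MI, >= 3 years ago", "mi", "three_plus_years_ago",
      1.35, event = "MI", timing = "three_plus_years_ago"),
  lvl("stroke_same_year", "Incident stroke, same year", "stroke", "same_year",
      47.08, event = "stroke", timing = "same_year"),
  lvl("stroke_1y", "Incident stroke, 1 year ago", "stroke", "one_year_ago",
      2.58, event = "stroke", timing = "one_year_ago"),
  lvl("stroke_2y", "Incident stroke, 2 years ago", "stroke", "two_years_ago",
      1.78, event = "stroke", timing = "two_years_ago"),
  lvl("stroke_3plus", "Incident stroke, >= 3 years ago", "stroke",
      "three_plus_years_ago", 1.49, event = "stroke",
      timing = "three_plus_years_ago"),
  lvl("crv_1y", "Incident CRV, 1 year ago", "crv", "one_year_ago", 1.66,
      event = "CRV", timing = "one_year_ago"),
  lvl("crv_2y", "Incident CRV, 2 years ago", "crv", "two_years_ago", 1.51,
      event = "CRV", timing = "two_years_ago"),
  lvl("crv_3plus", "Incident CRV, >= 3 years ago", "crv",
      "three_plus_years_ago", 1.32, event = "CRV",
      timing = "three_plus_years_ago"),
  lvl("diabetes_lt10y", "Diabetes < 10 years ago", "diabetes", "lt10y", 1.36,
      event = "diabetes", timing = "lt10y"),
  lvl("diabetes_ge10y", "Diabetes >= 10 years ago", "diabetes", "ge10y", 1.2,
      event = "diabetes", timing = "ge10y"),
  lvl("cancer_same_year", "Cancer, same year", "cancer", "same_year", 40.92,
      event = "cancer", timing = "same_year"),
  lvl("cancer_1y", "Cancer, 1 year ago", "cancer", "one_year_ago", 6.04,
      event = "cancer", timing = "one_year_ago"),
  lvl("cancer_2y", "Cancer, 2 years ago", "cancer", "two_years_ago", 3.03,
      event = "cancer", timing = "two_years_ago"),
  lvl("cancer_3y", "Cancer, 3 years ago", "cancer", "three_years_ago", 2.46,
      event = "cancer", timing = "three_years_ago"),
  lvl("cancer_4y", "Cancer, 4 years ago", "cancer", "four_years_ago", 2.23,
      event = "cancer", timing = "four_years_ago"),
  lvl("cancer_5plus", "Cancer, >= 5 years ago", "cancer", CAN_5PLUS, 1.69,
      event = "cancer", timing = "five_plus"),
  lvl("vd", "VD", "vd", "yes", 2.32, event = "VD", timing = "same_year"),
  lvl("nvd", "NVD", "nvd", "yes", 11.4, event = "NVD", timing = "same_year"),
  inter("mi_same_year_x_vd", "Same year MI and same year VD",
        list(list("mi", "same_year"), list("vd", "yes")), 0.03),
  inter("stroke_same_year_x_vd", "Same year stroke and same year VD",
        list(list("stroke", "same_year"), list("vd", "yes")), 0.22),
  inter("cancer_same_year_x_nvd", "Same year cancer and same year NVD",
        list(list("cancer", "same_year"), list("nvd", "yes")), 0.35)
)

## with previous CVD
h1_wi <- list(
  icpt(0.19),
  lvl("male", "Male", "sex", "male", 0.87),
  lvl("ethnicity_black", "Black", "ethnicity", "black", 1.06),
  lvl("ethnicity_south_asian", "South Asian", "ethnicity", "south_asian", 1.21),
  lvl("ethnicity_other", "Other ethnicity", "ethnicity", "other", 1.09),
  lvl("townsend_q1", "Townsend quintile 1", "townsend", "q1", 0.91),
  lvl("townsend_q2", "Townsend quintile 2", "townsend", "q2", 0.95),
  lvl("townsend_q4", "Townsend quintile 4", "townsend", "q4", 1.06),
  lvl("townsend_q5", "Townsend quintile 5", "townsend", "q5", 1.15),
  lvl("smoking_former", "Former smoker", "smoking", "former", 1.06),
  lvl("smoking_current", "Current smoker", "smoking", "current", 1.13),
  lvl("pa_low", "Low physical activity", "physical_activity", "low", 1.25),
  lvl("pa_high", "High physical activity", "physical_activity", "high", 1.04),
  lvl("pa_missing", "Missing physical activity", "physical_activity", "missing", 1.17),
  lvl("diet_unhealthy", "Unhealthy diet", "diet", "unhealthy", 1.06),
  lvl("bmi_lt18.5", "BMI < 18.5", "bmi", "lt18.5", 1.43),
  lvl("bmi_25to30", "BMI 25-30", "bmi", "25to30", 1.04),
  lvl("bmi_30to35", "BMI 30-35", "bmi", "30to35", 1.14),
  lvl("bmi_35to40", "BMI 35-40", "bmi", "35to40", 1.21),
  lvl("bmi_ge40", "BMI >= 40", "bmi", "ge40", 1.34),
  cont("ln_creatinine",
       "Natural logarithm of creatinine (centred at 4.4; per 0.2 ln umol/L)",
       "creatinine", "log_linear", 1.02, center = 4.4, scale = 0.2),
  cont("sbp", "Systolic blood pressure (centred at 140; per 20 mmHg)", "sbp",
       "linear", 0.95, center = 140, scale = 20),
  lvl("antihypertensive", "On antihypertensive treatment",
      "antihypertensive", "yes", 1.11),
  lvl("severe_mental_illness", "Severe mental illness history",
      "severe_mental_illness", "yes", 1.39),
  lvl("prior_type1_diabetes", "Prior type 1 diabetes",
      "prior_type1_diabetes", "yes", 1.69),
  lvl("prior_cvd_pad_only", "Prior CVD: PAD only", "prior_cvd", "pad_only", 1.19),
  lvl("prior_cvd_stroke_only", "Prior CVD: stroke only", "prior_cvd",
      "stroke_only", 1.11),
  lvl("prior_cvd_other_chd_only", "Prior CVD: other CHD only", "prior_cvd",
      "other_chd_only", 1.27),
  lvl("prior_cvd_two_or_more", "Prior CVD: two or more", "prior_cvd",
      "two_or_more", 1.43),
  cont("age", "Current age (centred at 60; per 10 years)", "current_age",
       "linear", 1.25, center = 60, scale = 10),
  lvl("mi_same_year", "Incident MI, same year", "mi", "same_year", 47.33,
      event = "MI", timing = "same_year"),
  lvl("mi_1y", "Incident MI, 1 year ago", "mi", "one_year_ago", 1.71,
      event = "MI", timing = "one_year_ago"),
  lvl("mi_2y", "Incident MI, 2 years ago", "mi", "two_years_ago", 1.28,
      event = "MI", timing = "two_years_ago"),
  mrg("mi_3plus", "Incident MI, >= 3 years ago", "mi", "three_plus_years_ago",
      event = "MI", timing = "three_plus_years_ago"),
  lvl("stroke_same_year", "Incident stroke, same year", "stroke", "same_year",
      46.65, event = "stroke", timing = "same_year"),
  lvl("stroke_1y", "Incident stroke, 1 year ago", "stroke", "one_year_ago",
      2.19, event = "stroke", timing = "one_year_ago"),
  lvl("stroke_2y", "Incident stroke, 2 years ago", "stroke", "two_years_ago",
      1.52, event = "stroke", timing = "two_years_ago"),
  mrg("stroke_3plus", "Incident stroke, >= 3 years ago", "stroke",
      "three_plus_years_ago", event = "stroke",
      timing = "three_plus_years_ago"),
  lvl("crv_1y", "Incident CRV, 1 year ago", "crv", "one_year_ago", 1.54,
      event = "CRV", timing = "one_year_ago"),
  lvl("crv_2y", "Incident CRV, 2 years ago", "crv", "two_years_ago", 1.32,
      event = "CRV", timing = "two_years_ago"),
  mrg("crv_3plus", "Incident CRV, >= 3 years ago", "crv",
      "three_plus_years_ago", event = "CRV", timing = "three_plus_years_ago"),
  lvl("diabetes_lt10y", "Diabetes < 10 years ago", "diabetes", "lt10y", 1.36,
      event = "diabetes", timing = "lt10y"),
  lvl("diabetes_ge10y", "Diabetes >= 10 years ago", "diabetes", "ge10y", 1.22,
      event = "diabetes", timing = "ge10y"),
  lvl("cancer_same_year", "Cancer, same year", "cancer", "same_year", 24.59,
      event = "cancer", timing = "same_year"),
  lvl("cancer_1y", "Cancer, 1 year ago", "cancer", "one_year_ago", 3.81,
      event = "cancer", timing = "one_year_ago"),
  lvl("cancer_2y", "Cancer, 2 years ago", "cancer", "two_years_ago", 2.39,
      event = "cancer", timing = "two_years_ago"),
  lvl("cancer_3y", "Cancer, 3 years ago", "cancer", "three_years_ago", 2.09,
      event = "cancer", timing = "three_years_ago"),
  lvl("cancer_4y", "Cancer, 4 years ago", "cancer", "four_years_ago", 1.92,
      event = "cancer", timing = "four_years_ago"),
  lvl("cancer_5plus", "Cancer, >= 5 years ago", "cancer", CAN_5PLUS, 1.6,
      event = "cancer", timing = "five_plus"),
  lvl("vd", "VD", "vd", "yes", 2.38, event = "VD", timing = "same_year"),
  lvl("nvd", "NVD", "nvd", "yes", 9.1, event = "NVD", timing = "same_year"),
  inter("mi_same_year_x_vd", "Same year MI and same year VD",
        list(list("mi", "same_year"), list("vd", "yes")), 0.02),
  inter("stroke_same_year_x_vd", "Same year stroke and same year VD",
        list(list("stroke", "same_year"), list("vd", "yes")), 0.09),
  inter("cancer_same_year_x_nvd", "Same year cancer and same year NVD",
        list(list("cancer", "same_year"), list("nvd", "yes")), 0.37)
)

## ---- Hospital part 2 (conditional cost; additive GBP) ----------------------
## without previous CVD
h2_wo <- list(
  icpt(2102, 23),
  lvl("male", "Male", "sex", "male", -65, 14),
  lvl("ethnicity_black", "Black", "ethnicity", "black", -117, 68),
  lvl("ethnicity_south_asian", "South Asian", "ethnicity", "south_asian", -168, 48),
  lvl("ethnicity_other", "Other ethnicity", "ethnicity", "other", -165, 49),
  lvl("townsend_q1", "Townsend quintile 1", "townsend", "q1", -81, 20),
  lvl("townsend_q2", "Townsend quintile 2", "townsend", "q2", -55, 22),
  lvl("townsend_q4", "Townsend quintile 4", "townsend", "q4", 24, 27),
  lvl("townsend_q5", "Townsend quintile 5", "townsend", "q5", 94, 27),
  lvl("smoking_former", "Former smoker", "smoking", "former", 40, 15),
  lvl("smoking_current", "Current smoker", "smoking", "current", 183, 24),
  lvl("pa_low", "Low physical activity", "physical_activity", "low", 110, 23),
  lvl("pa_high", "High physical activity", "physical_activity", "high", -12, 16),
  lvl("pa_missing", "Missing physical activity", "physical_activity", "missing", 72, 20),
  lvl("bmi_lt18.5", "BMI < 18.5", "bmi", "lt18.5", 298, 169),
  lvl("bmi_25to30", "BMI 25-30", "bmi", "25to30", 68, 16),
  lvl("bmi_30to35", "BMI 30-35", "bmi", "30to35", 239, 20),
  lvl("bmi_35to40", "BMI 35-40", "bmi", "35to40", 451, 35),
  lvl("bmi_ge40", "BMI >= 40", "bmi", "ge40", 649, 66),
  cont("ldl", "LDL cholesterol (centred at 3.6; per 1 mmol/L)", "ldl",
       "linear", -36, 8, center = 3.6, scale = 1),
  lvl("antihypertensive", "On antihypertensive treatment",
      "antihypertensive", "yes", 141, 20),
  lvl("severe_mental_illness", "Severe mental illness history",
      "severe_mental_illness", "yes", 193, 25),
  lvl("prior_type1_diabetes", "Prior type 1 diabetes",
      "prior_type1_diabetes", "yes", 702, 119),
  cont("age", "Current age (centred at 60; per 10 years)", "current_age",
       "linear", 173, 9, center = 60, scale = 10),
  lvl("mi_same_year", "Incident MI, same year", "mi", "same_year", 3054, 167,
      event = "MI", timing = "same_year"),
  lvl("mi_1y", "Incident MI, 1 year ago", "mi", "one_year_ago", 670, 153,
      event = "MI", timing = "one_year_ago"),
  lvl("mi_2y", "Incident MI, 2 years ago", "mi", "two_years_ago", 304, 117,
      event = "MI", timing = "two_years_ago"),
  mrg("mi_3plus", "Incident MI, >= 3 years ago", "mi", "three_plus_years_ago",
      event = "MI", timing = "three_plus_years_ago"),
  lvl("stroke_same_year", "Incident stroke, same year", "stroke", "same_year",
      4485, 142, event = "stroke", timing = "same_year"),
  lvl("stroke_1y", "Incident stroke, 1 year ago", "stroke", "one_year_ago",
      2192, 296, event = "stroke", timing = "one_year_ago"),
  lvl("stroke_2y", "Incident stroke, 2 years ago", "stroke", "two_years_ago",
      833, 137, event = "stroke", timing = "two_years_ago"),
  mrg("stroke_3plus", "Incident stroke, >= 3 years ago", "stroke",
      "three_plus_years_ago", event = "stroke",
      timing = "three_plus_years_ago"),
  lvl("crv_same_year", "Incident CRV, same year", "crv", "same_year", 5186, 114,
      event = "CRV", timing = "same_year"),
  lvl("crv_1y", "Incident CRV, 1 year ago", "crv", "one_year_ago", 137, 82,
      event = "CRV", timing = "one_year_ago"),
  mrg("crv_2y", "Incident CRV, 2 years ago", "crv", "two_years_ago",
      event = "CRV", timing = "two_years_ago"),
  mrg("crv_3plus", "Incident CRV, >= 3 years ago", "crv",
      "three_plus_years_ago", event = "CRV", timing = "three_plus_years_ago"),
  lvl("diabetes_lt10y", "Diabetes < 10 years ago", "diabetes", "lt10y", 274, 35,
      event = "diabetes", timing = "lt10y"),
  lvl("diabetes_ge10y", "Diabetes >= 10 years ago", "diabetes", "ge10y", 158, 51,
      event = "diabetes", timing = "ge10y"),
  lvl("cancer_same_year", "Cancer, same year", "cancer", "same_year", 5380, 56,
      event = "cancer", timing = "same_year"),
  lvl("cancer_1y", "Cancer, 1 year ago", "cancer", "one_year_ago", 4620, 86,
      event = "cancer", timing = "one_year_ago"),
  lvl("cancer_2y", "Cancer, 2 years ago", "cancer", "two_years_ago", 2332, 88,
      event = "cancer", timing = "two_years_ago"),
  lvl("cancer_3y", "Cancer, 3 years ago", "cancer", "three_years_ago", 1899, 89,
      event = "cancer", timing = "three_years_ago"),
  lvl("cancer_4y", "Cancer, 4 years ago", "cancer", "four_years_ago", 1502, 86,
      event = "cancer", timing = "four_years_ago"),
  lvl("cancer_5plus", "Cancer, >= 5 years ago", "cancer", CAN_5PLUS, 1159, 38,
      event = "cancer", timing = "five_plus"),
  lvl("vd", "VD", "vd", "yes", 4318, 491, event = "VD", timing = "same_year"),
  lvl("nvd", "NVD", "nvd", "yes", 6792, 145, event = "NVD", timing = "same_year"),
  inter("mi_same_year_x_crv_same_year", "Same year MI and same year CRV",
        list(list("mi", "same_year"), list("crv", "same_year")), -3848, 227),
  inter("mi_same_year_x_vd", "Same year MI and same year VD",
        list(list("mi", "same_year"), list("vd", "yes")), -4694, 670),
  inter("stroke_same_year_x_vd", "Same year stroke and same year VD",
        list(list("stroke", "same_year"), list("vd", "yes")), -4171, 685),
  inter("cancer_same_year_x_nvd", "Same year cancer and same year NVD",
        list(list("cancer", "same_year"), list("nvd", "yes")), -1725, 291)
)

## with previous CVD
h2_wi <- list(
  icpt(2326, 119),
  lvl("male", "Male", "sex", "male", -125, 54),
  lvl("ethnicity_black", "Black", "ethnicity", "black", -412, 128),
  lvl("ethnicity_south_asian", "South Asian", "ethnicity", "south_asian", -426, 102),
  lvl("ethnicity_other", "Other ethnicity", "ethnicity", "other", -246, 145),
  lvl("smoking_former", "Former smoker", "smoking", "former", 8, 45),
  lvl("smoking_current", "Current smoker", "smoking", "current", 276, 85),
  lvl("pa_low", "Low physical activity", "physical_activity", "low", 415, 74),
  lvl("pa_high", "High physical activity", "physical_activity", "high", -13, 46),
  lvl("pa_missing", "Missing physical activity", "physical_activity", "missing", 156, 51),
  lvl("bmi_lt18.5", "BMI < 18.5", "bmi", "lt18.5", 1007, 796),
  lvl("bmi_25to30", "BMI 25-30", "bmi", "25to30", 16, 50),
  lvl("bmi_30to35", "BMI 30-35", "bmi", "30to35", 177, 58),
  lvl("bmi_35to40", "BMI 35-40", "bmi", "35to40", 381, 87),
  lvl("bmi_ge40", "BMI >= 40", "bmi", "ge40", 840, 178),
  cont("ln_creatinine",
       "Natural logarithm of creatinine (centred at 4.4; per 0.2 ln umol/L)",
       "creatinine", "log_linear", 107, 24, center = 4.4, scale = 0.2),
  lvl("severe_mental_illness", "Severe mental illness history",
      "severe_mental_illness", "yes", 227, 66),
  lvl("prior_type1_diabetes", "Prior type 1 diabetes",
      "prior_type1_diabetes", "yes", 792, 148),
  lvl("prior_cvd_pad_only", "Prior CVD: PAD only", "prior_cvd", "pad_only",
      498, 122),
  lvl("prior_cvd_stroke_only", "Prior CVD: stroke only", "prior_cvd",
      "stroke_only", 113, 118),
  lvl("prior_cvd_other_chd_only", "Prior CVD: other CHD only", "prior_cvd",
      "other_chd_only", 105, 106),
  lvl("prior_cvd_two_or_more", "Prior CVD: two or more", "prior_cvd",
      "two_or_more", 381, 114),
  cont("age", "Current age (centred at 60; per 10 years)", "current_age",
       "linear", 121, 31, center = 60, scale = 10),
  lvl("mi_same_year", "Incident MI, same year", "mi", "same_year", 3965, 241,
      event = "MI", timing = "same_year"),
  lvl("mi_1y", "Incident MI, 1 year ago", "mi", "one_year_ago", 1011, 303,
      event = "MI", timing = "one_year_ago"),
  lvl("mi_2y", "Incident MI, 2 years ago", "mi", "two_years_ago", 696, 171,
      event = "MI", timing = "two_years_ago"),
  mrg("mi_3plus", "Incident MI, >= 3 years ago", "mi", "three_plus_years_ago",
      event = "MI", timing = "three_plus_years_ago"),
  lvl("stroke_same_year", "Incident stroke, same year", "stroke", "same_year",
      4591, 208, event = "stroke", timing = "same_year"),
  lvl("stroke_1y", "Incident stroke, 1 year ago", "stroke", "one_year_ago",
      1561, 260, event = "stroke", timing = "one_year_ago"),
  mrg("stroke_2y", "Incident stroke, 2 years ago", "stroke", "two_years_ago",
      event = "stroke", timing = "two_years_ago"),
  mrg("stroke_3plus", "Incident stroke, >= 3 years ago", "stroke",
      "three_plus_years_ago", event = "stroke",
      timing = "three_plus_years_ago"),
  lvl("crv_same_year", "Incident CRV, same year", "crv", "same_year", 5117, 146,
      event = "CRV", timing = "same_year"),
  lvl("crv_1y", "Incident CRV, 1 year ago", "crv", "one_year_ago", 599, 192,
      event = "CRV", timing = "one_year_ago"),
  lvl("crv_2y", "Incident CRV, 2 years ago", "crv", "two_years_ago", 4, 110,
      event = "CRV", timing = "two_years_ago"),
  mrg("crv_3plus", "Incident CRV, >= 3 years ago", "crv",
      "three_plus_years_ago", event = "CRV", timing = "three_plus_years_ago"),
  lvl("diabetes_lt10y", "Diabetes < 10 years ago", "diabetes", "lt10y", 408, 80,
      event = "diabetes", timing = "lt10y"),
  mrg("diabetes_ge10y", "Diabetes >= 10 years ago", "diabetes", "ge10y",
      event = "diabetes", timing = "ge10y"),
  lvl("cancer_same_year", "Cancer, same year", "cancer", "same_year", 5160, 150,
      event = "cancer", timing = "same_year"),
  lvl("cancer_1y", "Cancer, 1 year ago", "cancer", "one_year_ago", 3475, 181,
      event = "cancer", timing = "one_year_ago"),
  lvl("cancer_2y", "Cancer, 2 years ago", "cancer", "two_years_ago", 1863, 172,
      event = "cancer", timing = "two_years_ago"),
  lvl("cancer_3y", "Cancer, 3 years ago", "cancer", "three_years_ago", 1601, 176,
      event = "cancer", timing = "three_years_ago"),
  lvl("cancer_4y", "Cancer, 4 years ago", "cancer", "four_years_ago", 947, 75,
      event = "cancer", timing = "four_years_ago"),
  mrg("cancer_5plus", "Cancer, >= 5 years ago", "cancer", CAN_5PLUS,
      event = "cancer", timing = "five_plus"),
  lvl("vd", "VD", "vd", "yes", 4749, 420, event = "VD", timing = "same_year"),
  lvl("nvd", "NVD", "nvd", "yes", 6412, 260, event = "NVD", timing = "same_year"),
  inter("mi_same_year_x_crv_same_year", "Same year MI and same year CRV",
        list(list("mi", "same_year"), list("crv", "same_year")), -3358, 364),
  inter("mi_same_year_x_vd", "Same year MI and same year VD",
        list(list("mi", "same_year"), list("vd", "yes")), -4874, 722),
  inter("stroke_same_year_x_vd", "Same year stroke and same year VD",
        list(list("stroke", "same_year"), list("vd", "yes")), -4308, 691),
  inter("cancer_same_year_x_nvd", "Same year cancer and same year NVD",
        list(list("cancer", "same_year"), list("nvd", "yes")), -1529, 617)
)

crv_rule <- list(list(when = list(field = "crv", levels = list("same_year")),
                      probability = 1))

note <- paste("Published annual healthcare cost models for UK adults.",
              "Part-1 estimates are odds (intercept) or odds ratios; all",
              "other estimates are additive 2020 UK GBP.",
              "merged_with_preceding marks temporal categories merged during",
              "model selection (coefficient of the preceding category).")

fixtures <- list(
  without_cvd = list(
    schema_version = "1.0", currency = "GBP", price_year = 2020, note = note,
    models = list(
      list(stratum = "without_cvd", service = "primary",
           scale = "additive_gbp", certainty_rules = list(),
           terms = primary_wo),
      list(stratum = "without_cvd", service = "hospital_part1",
           scale = "log_odds", certainty_rules = crv_rule, terms = h1_wo),
      list(stratum = "without_cvd", service = "hospital_part2",
           scale = "additive_gbp", certainty_rules = list(), terms = h2_wo)
    )
  ),
  with_cvd = list(
    schema_version = "1.0", currency = "GBP", price_year = 2020, note = note,
    models = list(
      list(stratum = "with_cvd", service = "primary",
           scale = "additive_gbp", certainty_rules = list(),
           terms = primary_wi),
      list(stratum = "with_cvd", service = "hospital_part1",
           scale = "log_odds", certainty_rules = crv_rule, terms = h1_wi),
      list(stratum = "with_cvd", service = "hospital_part2",
           scale = "additive_gbp", certainty_rules = list(), terms = h2_wi)
    )
  )
)

cnt <- function(tt) {
  np <- sum(vapply(tt, function(x) !isTRUE(x$merged_with_preceding) &&
                     x$kind != "intercept", logical(1)))
  nm <- sum(vapply(tt, function(x) isTRUE(x$merged_with_preceding), logical(1)))
  c(printed = np, merged = nm)
}
for (nm in names(fixtures)) {
  out <- sprintf("inst/extdata/published_models_2020_%s.json", nm)
  jsonlite::write_json(fixtures[[nm]], out, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  for (m in fixtures[[nm]]$models)
    cat(m$stratum, m$service, cnt(m$terms), "\n")
  cat(out, "bytes:", file.size(out), "md5:", unname(tools::md5sum(out)), "\n")
}
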