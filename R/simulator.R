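# Synthetic cohort and person-year cost panel generator.
#
# The simulator emulates the structure the cost models assume: baseline
# covariates drawn from the published cohort's marginal distributions, annual
# periods anchored at recruitment, first-occurrence events with absorbing
# death, annual primary care costs with mean given by the one-part linear
# predictor, and annual hospital costs as Bernoulli(any cost) x positive
# conditional cost with means given by the two-part predictors. Covariates are
# sampled independently (no correlation structure) - a documented limitation.

# Baseline marginal distributions (hospital-analysis columns of the published
# cohort description). Categorical proportions are renormalised after folding
# levels that carry no model coefficient (Townsend, smoking, diet, BMI
# "missing") into the reference level; physical activity keeps its modelled
# "missing" category.
.baseline_marginals <- list(
  without_cvd = list(
    male = 0.439,
    ethnicity = c(white = 94.0, black = 1.6, south_asian = 1.6, other = 2.2,
                  missing = 0.5),
    townsend = c(q1 = 37.4, q2 = 20.1, q3 = 16.4, q4 = 14.5, q5 = 11.7),
    smoking = c(never = 56.5, former = 33.2, current = 10.3),
    physical_activity = c(low = 14.8, moderate = 32.9, high = 32.7,
                          missing = 19.6),
    diet = c(healthy = 66.4, unhealthy = 33.5),
    bmi = c(lt18.5 = 0.5, `18.5to25` = 34.1, `25to30` = 42.3, `30to35` = 16.7,
            `35to40` = 4.6, ge40 = 1.8),
    age = c(mean = 56.0, sd = 8.1),
    ldl = c(mean = 3.6, sd = 0.8),
    hdl = c(mean = 1.5, sd = 0.4),
    creatinine = c(mean = 71.5, sd = 15.1),
    sbp = c(mean = 137.8, sd = 18.6),
    dbp = c(mean = 82.4, sd = 10.1),
    antihypertensive = 0.162,
    type1_diabetes = 0.006,
    type2_diabetes = 0.043,
    prior_cancer = 0.074,
    severe_mental_illness = 0.081,
    prior_cvd = c(none = 1)
  ),
  with_cvd = list(
    male = 0.589,
    ethnicity = c(white = 94.5, black = 1.3, south_asian = 1.8, other = 1.7,
                  missing = 0.6),
    townsend = c(q1 = 33.1, q2 = 19.1, q3 = 15.8, q4 = 16.0, q5 = 16.0),
    smoking = c(never = 44.2, former = 43.6, current = 12.1),
    physical_activity = c(low = 17.6, moderate = 30.9, high = 29.3,
                          missing = 22.2),
    diet = c(healthy = 64.8, unhealthy = 35.2),
    bmi = c(lt18.5 = 0.4, `18.5to25` = 24.4, `25to30` = 41.7, `30to35` = 22.8,
            `35to40` = 7.5, ge40 = 3.2),
    age = c(mean = 60.4, sd = 7.0),
    ldl = c(mean = 3.1, sd = 0.9),
    hdl = c(mean = 1.3, sd = 0.4),
    creatinine = c(mean = 77.0, sd = 19.8),
    sbp = c(mean = 138.9, sd = 18.9),
    dbp = c(mean = 80.9, sd = 10.5),
    antihypertensive = 0.457,
    type1_diabetes = 0.024,
    type2_diabetes = 0.119,
    prior_cancer = 0.102,
    severe_mental_illness = 0.110,
    prior_cvd = c(mi_only = 3.6, stroke_only = 9.0, pad_only = 11.9,
                  other_chd_only = 50.6, two_or_more = 25.0)
  )
)

#' Simulation configuration
#'
#' Defaults state the simulated world: per-year event hazards calibrated so
#' cumulative incidence over the published cohort's 7.1-year average follow-up
#' matches its reported figures (MI 1.4%, stroke 1.2%, CRV 1.8%, vascular
#' death 0.6%, non-vascular death 2.3%, diabetes 2.1%, cancer 6.7%), an
#' 11.4% with-CVD mix, gamma cost noise (right-skewed like real cost data) and
#' the 13.7% registration-gap rate of the primary care records.
#'
#' @param n_participants cohort size.
#' @param horizon_years annual periods per person (before death truncation).
#' @param stratum_mix proportion of the cohort with previous CVD.
#' @param hazards named per-year first-occurrence probabilities (mi, stroke,
#'   crv, diabetes, cancer, vd, nvd).
#' @param co_occurrence conditional same-year probabilities that induce the
#'   event co-occurrences the models carry interactions for: probability of
#'   same-year CRV given incident MI, and additive same-year death-risk boosts
#'   after MI/stroke (vascular) and same-year cancer (non-vascular).
#' @param primary_noise,hospital_noise list(family, shape): "gamma" (shape =
#'   gamma shape; variance = mean^2/shape) or "lognormal" (shape = sdlog).
#' @param registration_gap_probability probability that a person-year's primary
#'   care record is excluded for a registration gap.
#' @param epsilon_floor_gbp floor for non-positive generative means under the
#'   identity link.
#' @param seed integer seed; all simulator draws are reproducible given the
#'   config.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 10000,
                              horizon_years = 7,
                              stratum_mix = 0.114,
                              hazards = list(mi = 0.002, stroke = 0.0017,
                                             crv = 0.0026, diabetes = 0.003,
                                             cancer = 0.0097, vd = 0.00085,
                                             nvd = 0.0033),
                              co_occurrence = list(crv_given_mi = 0.3,
                                                   vd_given_mi = 0.05,
                                                   vd_given_stroke = 0.05,
                                                   nvd_given_cancer = 0.05),
                              primary_noise = list(family = "gamma", shape = 1),
                              hospital_noise = list(family = "gamma", shape = 0.8),
                              registration_gap_probability = 0.137,
                              epsilon_floor_gbp = 1,
                              seed = 1) {
  stopifnot(n_participants >= 1, horizon_years >= 1,
            stratum_mix >= 0, stratum_mix <= 1,
            registration_gap_probability >= 0,
            registration_gap_probability < 1,
            primary_noise$shape > 0, hospital_noise$shape > 0)
  hz <- unlist(hazards)
  if (any(hz < 0 | hz > 1)) stop("hazards must be probabilities in [0, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 horizon_years = as.integer(horizon_years),
                 stratum_mix = stratum_mix, hazards = hazards,
                 co_occurrence = co_occurrence,
                 primary_noise = primary_noise,
                 hospital_noise = hospital_noise,
                 registration_gap_probability = registration_gap_probability,
                 epsilon_floor_gbp = epsilon_floor_gbp,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

sample_cat <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights / sum(weights))
}

#' Sample a baseline cohort
#'
#' Draws covariate profiles whose categorical fields follow the published
#' cohort's marginal proportions for the given stratum and whose biomarkers
#' follow normal distributions with the published means/SDs, truncated to
#' physiological ranges. Fields are sampled independently.
#'
#' @param n number of participants.
#' @param stratum "without_cvd" or "with_cvd".
#' @param seed integer seed.
#' @return data.frame, one row per person: person_id, stratum and the
#'   [covariate_profile()] fields.
#' @export
sample_baseline <- function(n, stratum = c("without_cvd", "with_cvd"),
                            seed = 1) {
  stratum <- match.arg(stratum)
  if (n < 1) stop("n must be >= 1")
  mg <- .baseline_marginals[[stratum]]
  with_seed(seed, {
    prior_t1 <- stats::runif(n) < mg$type1_diabetes
    prior_t2 <- !prior_t1 & stats::runif(n) < mg$type2_diabetes
    prior_can <- stats::runif(n) < mg$prior_cancer
    data.frame(
      person_id = seq_len(n),
      stratum = stratum,
      sex = ifelse(stats::runif(n) < mg$male, "male", "female"),
      ethnicity = sample_cat(n, mg$ethnicity),
      townsend_quintile = sample_cat(n, mg$townsend),
      smoking = sample_cat(n, mg$smoking),
      physical_activity = sample_cat(n, mg$physical_activity),
      diet = sample_cat(n, mg$diet),
      bmi_category = sample_cat(n, mg$bmi),
      ldl_mmol_per_l = rtrunc_norm(n, mg$ldl["mean"], mg$ldl["sd"], lo = 0.5),
      hdl_mmol_per_l = rtrunc_norm(n, mg$hdl["mean"], mg$hdl["sd"], lo = 0.4),
      creatinine_umol_per_l = rtrunc_norm(n, mg$creatinine["mean"],
                                          mg$creatinine["sd"], lo = 25),
      sbp_mmhg = rtrunc_norm(n, mg$sbp["mean"], mg$sbp["sd"], lo = 70, hi = 250),
      dbp_mmhg = rtrunc_norm(n, mg$dbp["mean"], mg$dbp["sd"], lo = 40, hi = 150),
      on_antihypertensive = stats::runif(n) < mg$antihypertensive,
      severe_mental_illness = stats::runif(n) < mg$severe_mental_illness,
      prior_type1_diabetes = prior_t1,
      prior_type2_diabetes = prior_t2,
      years_since_diabetes_diagnosis_at_entry =
        ifelse(prior_t1 | prior_t2, stats::runif(n, 0, 20), NA_real_),
      prior_cancer = prior_can,
      years_since_cancer_diagnosis_at_entry =
        ifelse(prior_can, stats::runif(n, 0, 15), NA_real_),
      prior_cvd_category = sample_cat(n, mg$prior_cvd),
      age_at_entry_years = rtrunc_norm(n, mg$age["mean"], mg$age["sd"],
                                       lo = 40, hi = 70),
      stringsAsFactors = FALSE
    )
  })
}

#' Convert a cohort row to a covariate profile
#'
#' @param cohort data.frame from [sample_baseline()].
#' @param i row index.
#' @return A [covariate_profile()].
#' @export
cohort_profile <- function(cohort, i) {
  r <- cohort[i, ]
  covariate_profile(
    sex = r$sex, ethnicity = r$ethnicity,
    townsend_quintile = r$townsend_quintile, smoking = r$smoking,
    physical_activity = r$physical_activity, diet = r$diet,
    bmi_category = r$bmi_category, ldl_mmol_per_l = r$ldl_mmol_per_l,
    hdl_mmol_per_l = r$hdl_mmol_per_l,
    creatinine_umol_per_l = r$creatinine_umol_per_l,
    sbp_mmhg = r$sbp_mmhg, dbp_mmhg = r$dbp_mmhg,
    on_antihypertensive = r$on_antihypertensive,
    severe_mental_illness = r$severe_mental_illness,
    prior_type1_diabetes = r$prior_type1_diabetes,
    prior_type2_diabetes = r$prior_type2_diabetes,
    years_since_diabetes_diagnosis_at_entry =
      if (is.na(r$years_since_diabetes_diagnosis_at_entry)) NULL
      else r$years_since_diabetes_diagnosis_at_entry,
    prior_cancer = r$prior_cancer,
    years_since_cancer_diagnosis_at_entry =
      if (is.na(r$years_since_cancer_diagnosis_at_entry)) NULL
      else r$years_since_cancer_diagnosis_at_entry,
    prior_cvd_category = r$prior_cvd_category,
    age_at_entry_years = r$age_at_entry_years
  )
}

#' Simulate first-occurrence events with absorbing death
#'
#' Per annual period, each event that has not yet occurred fires with its
#' per-year hazard; incident MI raises the same-year CRV probability and
#' same-year MI/stroke raise the vascular-death probability, inducing the event
#' co-occurrences the models carry interaction terms for. Vascular and
#' non-vascular death are mutually exclusive and absorbing: the death year is
#' the person's last annual period. People with baseline diabetes or cancer are
#' not at risk of the corresponding incident event.
#'
#' @param cohort data.frame from [sample_baseline()].
#' @param config a [simulation_config()].
#' @return data.frame: person_id, first-occurrence year indices (`mi_year`,
#'   `stroke_year`, `crv_year`, `diabetes_year`, `cancer_year`, `vd_year`,
#'   `nvd_year`; NA = never) and `n_years`, the number of annual periods the
#'   person contributes.
#' @export
simulate_events <- function(cohort, config) {
  n <- nrow(cohort)
  hz <- config$hazards
  co <- config$co_occurrence
  with_seed(config$seed + 1L, {
    ev <- data.frame(person_id = cohort$person_id,
                     mi_year = NA_integer_, stroke_year = NA_integer_,
                     crv_year = NA_integer_, diabetes_year = NA_integer_,
                     cancer_year = NA_integer_, vd_year = NA_integer_,
                     nvd_year = NA_integer_)
    dead <- rep(FALSE, n)
    at_risk_diabetes <- !(cohort$prior_type1_diabetes | cohort$prior_type2_diabetes)
    at_risk_cancer <- !cohort$prior_cancer
    for (y in seq_len(config$horizon_years) - 1L) {
      alive <- !dead
      fire <- function(prob, not_yet) alive & not_yet & stats::runif(n) < prob
      mi_now <- fire(hz$mi, is.na(ev$mi_year))
      ev$mi_year[mi_now] <- y
      p_crv <- ifelse(ev$mi_year %in% y & !is.na(ev$mi_year),
                      pmin(1, co$crv_given_mi %||% hz$crv), hz$crv)
      crv_now <- alive & is.na(ev$crv_year) & stats::runif(n) < p_crv
      ev$crv_year[crv_now] <- y
      stroke_now <- fire(hz$stroke, is.na(ev$stroke_year))
      ev$stroke_year[stroke_now] <- y
      dia_now <- fire(hz$diabetes, at_risk_diabetes & is.na(ev$diabetes_year))
      ev$diabetes_year[dia_now] <- y
      can_now <- fire(hz$cancer, at_risk_cancer & is.na(ev$cancer_year))
      ev$cancer_year[can_now] <- y
      p_vd <- hz$vd +
        ifelse(mi_now, co$vd_given_mi %||% 0, 0) +
        ifelse(stroke_now, co$vd_given_stroke %||% 0, 0)
      p_nvd <- hz$nvd + ifelse(can_now, co$nvd_given_cancer %||% 0, 0)
      u <- stats::runif(n)
      vd_now <- alive & u < p_vd
      nvd_now <- alive & !vd_now & u < p_vd + p_nvd
      ev$vd_year[vd_now] <- y
      ev$nvd_year[nvd_now] <- y
      dead <- dead | vd_now | nvd_now
    }
    death_year <- pmin(ev$vd_year, ev$nvd_year, na.rm = TRUE)
    death_year[is.na(ev$vd_year) & is.na(ev$nvd_year)] <- NA_integer_
    ev$n_years <- ifelse(is.na(death_year), config$horizon_years,
                         death_year + 1L)
    ev
  })
}

# Vectorised duration categories (NA first year = "none").
.vec_duration <- function(first_year, current_year, kind) {
  d <- current_year - first_year
  out <- rep("none", length(current_year))
  if (kind %in% c("MI", "stroke", "CRV")) {
    out[!is.na(d) & d == 0] <- "same_year"
    out[!is.na(d) & d == 1] <- "one_year_ago"
    out[!is.na(d) & d == 2] <- "two_years_ago"
    out[!is.na(d) & d >= 3] <- "three_plus_years_ago"
  } else if (kind == "diabetes") {
    out[!is.na(d) & d < 10] <- "lt10y"
    out[!is.na(d) & d >= 10] <- "ge10y"
  } else {
    out[!is.na(d) & d == 0] <- "same_year"
    out[!is.na(d) & d == 1] <- "one_year_ago"
    out[!is.na(d) & d == 2] <- "two_years_ago"
    out[!is.na(d) & d == 3] <- "three_years_ago"
    out[!is.na(d) & d == 4] <- "four_years_ago"
    out[!is.na(d) & d >= 5 & d < 10] <- "five_to_ten"
    out[!is.na(d) & d >= 10] <- "ten_plus"
  }
  out
}

#' Expand a cohort and its events into a person-year model frame
#'
#' One row per annual period actually observed (death truncates), with the
#' canonical model-frame fields used by the coefficient fixtures.
#'
#' @param cohort data.frame from [sample_baseline()].
#' @param events data.frame from [simulate_events()].
#' @return data.frame person-year panel skeleton (no costs yet).
#' @export
build_panel <- function(cohort, events) {
  stopifnot(nrow(cohort) == nrow(events))
  idx <- rep(seq_len(nrow(cohort)), events$n_years)
  year <- sequence(events$n_years) - 1L
  co <- cohort[idx, ]
  ev <- events[idx, ]
  dia_first <- ifelse(co$prior_type1_diabetes | co$prior_type2_diabetes,
                      -floor(co$years_since_diabetes_diagnosis_at_entry),
                      ev$diabetes_year)
  can_first <- ifelse(co$prior_cancer,
                      pmin(-floor(co$years_since_cancer_diagnosis_at_entry),
                           ev$cancer_year, na.rm = TRUE),
                      ev$cancer_year)
  data.frame(
    person_id = co$person_id,
    stratum = co$stratum,
    year_index = year,
    sex = co$sex,
    ethnicity = co$ethnicity,
    townsend = co$townsend_quintile,
    smoking = co$smoking,
    physical_activity = co$physical_activity,
    diet = co$diet,
    bmi = co$bmi_category,
    ldl = co$ldl_mmol_per_l,
    hdl = co$hdl_mmol_per_l,
    creatinine = co$creatinine_umol_per_l,
    sbp = co$sbp_mmhg,
    dbp = co$dbp_mmhg,
    antihypertensive = ifelse(co$on_antihypertensive, "yes", "no"),
    severe_mental_illness = ifelse(co$severe_mental_illness, "yes", "no"),
    prior_type1_diabetes = ifelse(co$prior_type1_diabetes, "yes", "no"),
    prior_cvd = co$prior_cvd_category,
    current_age = co$age_at_entry_years + year,
    mi = .vec_duration(ev$mi_year, year, "MI"),
    stroke = .vec_duration(ev$stroke_year, year, "stroke"),
    crv = .vec_duration(ev$crv_year, year, "CRV"),
    diabetes = .vec_duration(dia_first, year, "diabetes"),
    cancer = .vec_duration(can_first, year, "cancer"),
    vd = ifelse(!is.na(ev$vd_year) & ev$vd_year == year, "yes", "no"),
    nvd = ifelse(!is.na(ev$nvd_year) & ev$nvd_year == year, "yes", "no"),
    observed_fraction = 1,
    stringsAsFactors = FALSE
  )
}

rpos_noise <- function(n, mu, noise) {
  if (noise$family == "gamma")
    stats::rgamma(n, shape = noise$shape, scale = mu / noise$shape)
  else if (noise$family == "lognormal")
    stats::rlnorm(n, meanlog = log(mu) - noise$shape^2 / 2, sdlog = noise$shape)
  else stop("unknown noise family: ", noise$family)
}

#' Simulate a person-year cost panel from cost models
#'
#' Generative inversion of the fitted models: annual primary care cost is drawn
#' from the configured positive noise family with mean equal to the one-part
#' linear predictor; the hospital any-cost indicator is Bernoulli with the
#' part-1 probability (respecting the same-year-CRV certainty rule) and the
#' conditional cost is drawn with mean equal to the part-2 linear predictor.
#' Non-positive generative means are floored at `epsilon_floor_gbp`.
#'
#' @param cohort data.frame from [sample_baseline()].
#' @param events data.frame from [simulate_events()].
#' @param models model map from [load_published_models()].
#' @param config a [simulation_config()].
#' @return Person-year panel data.frame: the [build_panel()] columns plus
#'   `primary_mean_gbp`, `primary_gbp`, `hospital_probability`,
#'   `hospital_any`, `hospital_gbp`. Attribute `seed` records the config seed.
#' @export
simulate_costs <- function(cohort, events, models, config) {
  panel <- build_panel(cohort, events)
  eps <- config$epsilon_floor_gbp
  panel$primary_mean_gbp <- NA_real_
  panel$hospital_probability <- NA_real_
  cond_mean <- numeric(nrow(panel))
  for (stratum in unique(panel$stratum)) {
    sel <- panel$stratum == stratum
    sub <- panel[sel, ]
    pm <- models[[paste0(stratum, ".primary")]]
    p1 <- models[[paste0(stratum, ".hospital_part1")]]
    p2 <- models[[paste0(stratum, ".hospital_part2")]]
    beta <- function(m) vapply(m$terms, `[[`, 0, "coefficient")
    mu_p <- drop(build_design_matrix(sub, pm) %*% beta(pm))
    if (any(!is.finite(mu_p))) stop("non-finite primary-care generative mean")
    eta <- drop(build_design_matrix(sub, p1) %*% beta(p1))
    prob <- stats::plogis(eta)
    prob[certainty_fires(sub, p1)] <- 1
    mu_h <- drop(build_design_matrix(sub, p2) %*% beta(p2))
    if (any(!is.finite(mu_h))) stop("non-finite hospital generative mean")
    panel$primary_mean_gbp[sel] <- pmax(eps, mu_p)
    panel$hospital_probability[sel] <- prob
    cond_mean[sel] <- pmax(eps, mu_h)
  }
  with_seed(config$seed + 2L, {
    panel$primary_gbp <- rpos_noise(nrow(panel), panel$primary_mean_gbp,
                                    config$primary_noise)
    panel$hospital_any <- as.integer(stats::runif(nrow(panel)) <
                                       panel$hospital_probability)
    panel$hospital_gbp <- panel$hospital_any *
      rpos_noise(nrow(panel), cond_mean, config$hospital_noise)
  })
  attr(panel, "seed") <- config$seed
  panel
}

#' Simulate a full panel in one call
#'
#' Samples the baseline cohort (mixing strata per `stratum_mix`), simulates
#' events and costs, and optionally applies registration gaps.
#'
#' @param models model map.
#' @param config a [simulation_config()].
#' @param registration_gaps apply [apply_registration_gaps()]?
#' @return Person-year panel.
#' @export
simulate_panel <- function(models, config = simulation_config(),
                           registration_gaps = FALSE) {
  n_with <- round(config$n_participants * config$stratum_mix)
  n_without <- config$n_participants - n_with
  parts <- list()
  if (n_without > 0)
    parts$wo <- sample_baseline(n_without, "without_cvd", seed = config$seed)
  if (n_with > 0) {
    wi <- sample_baseline(n_with, "with_cvd", seed = config$seed + 100003L)
    wi$person_id <- wi$person_id + n_without
    parts$wi <- wi
  }
  cohort <- do.call(rbind, unname(parts))
  events <- simulate_events(cohort, config)
  panel <- simulate_costs(cohort, events, models, config)
  if (registration_gaps) panel <- apply_registration_gaps(panel, config)
  panel
}

#' Pro-rata allocation of an admission's cost to annual periods
#'
#' Splits the total cost of a hospital admission across the annual periods it
#' spans, proportionally to the nights spent in each period, with a
#' largest-remainder correction on pennies so the shares sum to the input cost
#' exactly. Same-day admissions (0 nights) assign the full cost to the period
#' containing the admission date.
#'
#' @param admission list with `admission_date`, `discharge_date` (Date or
#'   ISO-8601 strings) and `total_cost_gbp`.
#' @param period_boundaries ascending Date vector of annual-period start dates;
#'   period k is `[boundaries[k], boundaries[k+1])`.
#' @return Named numeric vector of costs (GBP), one entry per overlapped
#'   period, named by period start date.
#' @export
allocate_admission_cost <- function(admission, period_boundaries) {
  adm <- as.Date(admission$admission_date)
  dis <- as.Date(admission$discharge_date)
  cost <- as.numeric(admission$total_cost_gbp)
  if (dis < adm) stop("discharge date precedes admission date")
  if (cost < 0) stop("admission cost must be non-negative")
  b <- as.Date(period_boundaries)
  if (is.unsorted(b, strictly = TRUE))
    stop("period_boundaries must be strictly ascending")
  k <- length(b) - 1
  if (k < 1) stop("need at least two period boundaries")
  starts <- b[-length(b)]
  ends <- b[-1]
  nights <- pmax(0, as.numeric(pmin(dis, ends) - pmax(adm, starts)))
  if (sum(nights) == 0) {
    # same-day admission: full cost to the period containing the admission date
    idx <- findInterval(as.numeric(adm), as.numeric(b))
    if (idx < 1 || idx > k) stop("admission outside all annual periods")
    shares <- numeric(k)
    shares[idx] <- cost
  } else {
    raw <- cost * nights / sum(nights)
    pennies <- floor(raw * 100)
    short <- max(0, round(cost * 100) - sum(pennies))
    frac <- raw * 100 - pennies
    if (short > 0) {
      give <- order(frac, decreasing = TRUE)[seq_len(short)]
      pennies[give] <- pennies[give] + 1
    }
    shares <- pennies / 100
  }
  names(shares) <- as.character(starts)
  shares[shares > 0 | nights > 0]
}

#' Mark person-years with primary care registration gaps
#'
#' Flags the configured fraction of person-years as missing linked primary care
#' data; flagged rows are excluded from primary-care estimation only (hospital
#' costs are unaffected).
#'
#' @param panel person-year panel.
#' @param config a [simulation_config()] (uses `registration_gap_probability`
#'   and `seed`).
#' @return The panel with a logical `primary_excluded` column.
#' @export
apply_registration_gaps <- function(panel, config) {
  p <- config$registration_gap_probability
  panel$primary_excluded <- if (p <= 0) rep(FALSE, nrow(panel)) else
    with_seed(config$seed + 3L, stats::runif(nrow(panel)) < p)
  panel
}
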