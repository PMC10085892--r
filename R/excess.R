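# Population-average excess annual costs via recycled prediction.
#
# The excess cost of an event at a given timing is the mean, over a reference
# population, of the difference between each member's predicted annual cost
# with the event set to that timing and with the event absent (all else equal;
# interactions involving the event follow it automatically). For the linear
# primary care model the difference is the same for every member (the sum of
# the active coefficients); for the two-part hospital model it varies with
# population composition.

.event_kinds <- c("MI", "stroke", "CRV", "VD", "NVD", "diabetes", "cancer")

# Timing categories reported per event (model-frame levels).
event_timings <- function(event) {
  switch(event,
    MI = , stroke = , CRV = c("same_year", "one_year_ago", "two_years_ago",
                              "three_plus_years_ago"),
    VD = , NVD = "same_year",
    diabetes = c("lt10y", "ge10y"),
    cancer = c("same_year", "one_year_ago", "two_years_ago", "three_years_ago",
               "four_years_ago", "five_to_ten", "ten_plus")
  )
}

# Return a copy of the state with one event forced to a timing (or removed).
set_event_timing <- function(state, event, timing) {
  event <- match.arg(event, .event_kinds)
  if (event %in% c("VD", "NVD")) {
    fld <- if (event == "VD") "vd_this_year" else "nvd_this_year"
    state[[fld]] <- !is.null(timing) && timing != "none"
    if (state$vd_this_year && state$nvd_this_year)
      stop("cannot set both vascular and non-vascular death in one year")
    return(state)
  }
  fld <- c(MI = "mi", stroke = "stroke", CRV = "crv",
           diabetes = "diabetes", cancer = "cancer")[[event]]
  timing <- timing %||% "none"
  if (!timing %in% .categorical_fields[[fld]])
    stop("invalid timing '", timing, "' for event ", event)
  state[[fld]] <- timing
  state
}

#' Mean excess annual cost of an event by recycled prediction
#'
#' For every population member, predicts the annual cost with the event set to
#' the given timing and with the event absent, and returns the mean difference.
#'
#' @param models model map from [load_published_models()].
#' @param population list of members, each a list with elements `profile` and
#'   (optionally) `state`; a bare `covariate_profile` is also accepted (state
#'   defaults to an event-free first year).
#' @param event one of "MI", "stroke", "CRV", "VD", "NVD", "diabetes",
#'   "cancer".
#' @param timing timing category for the event (see [event_timings()]).
#' @param service "primary" or "hospital".
#' @param stratum cohort stratum of the models to use.
#' @return Mean excess annual cost in GBP (unrounded).
#' @export
recycled_excess <- function(models, population, event, timing,
                            service = c("primary", "hospital"),
                            stratum = c("without_cvd", "with_cvd")) {
  service <- match.arg(service)
  stratum <- match.arg(stratum)
  event <- match.arg(event, .event_kinds)
  if (!length(population)) stop("population must be non-empty")
  pm <- models[[paste0(stratum, ".primary")]]
  p1 <- models[[paste0(stratum, ".hospital_part1")]]
  p2 <- models[[paste0(stratum, ".hospital_part2")]]
  diffs <- vapply(population, function(member) {
    if (inherits(member, "covariate_profile"))
      member <- list(profile = member)
    validate_profile(member$profile, stratum)
    st <- member$state %||% event_state(member$profile, year_index = 0)
    st_on <- set_event_timing(st, event, timing)
    st_off <- set_event_timing(st, event, "none")
    pick <- function(s) {
      if (service == "primary") {
        as.numeric(predict_primary_cost(
          encode_design_row(member$profile, s, pm), pm))
      } else {
        predict_hospital_cost(
          encode_design_row(member$profile, s, p1), p1,
          encode_design_row(member$profile, s, p2), p2)$hospital_gbp
      }
    }
    pick(st_on) - pick(st_off)
  }, numeric(1))
  mean(diffs)
}

#' Round to the nearest ten pounds
#'
#' Nearest multiple of 10, halves away from zero (the convention of the
#' published excess-cost table).
#'
#' @param x numeric vector of amounts in GBP.
#' @return `x` rounded to multiples of 10.
#' @export
round_to_ten <- function(x) {
  sign(x) * floor(abs(x) / 10 + 0.5) * 10
}

#' Percentile bootstrap confidence interval
#'
#' Resamples population members (participants; all of a participant's annual
#' periods move together) with replacement and returns the 2.5th/97.5th
#' percentile interval of the statistic. Deterministic given `seed`.
#'
#' @param statistic function of a population (same type as `population`)
#'   returning a scalar.
#' @param population list or data.frame of participants (data.frame rows are
#'   resampled).
#' @param n_resamples number of bootstrap resamples (>= 2); the published
#'   analyses used 1000.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`. A degenerate (constant)
#'   statistic yields a zero-width interval with a warning.
#' @export
bootstrap_ci <- function(statistic, population, n_resamples = 1000,
                         seed = 1, conf = 0.95) {
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  n <- if (is.data.frame(population)) nrow(population) else length(population)
  if (n < 1) stop("population must be non-empty")
  take <- if (is.data.frame(population))
    function(idx) population[idx, , drop = FALSE]
  else
    function(idx) population[idx]
  stats <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      statistic(take(sample.int(n, n, replace = TRUE)))
    }, numeric(1))
  })
  if (max(stats) - min(stats) == 0)
    warning("degenerate statistic: zero-width bootstrap interval")
  a <- (1 - conf) / 2
  q <- stats::quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Excess annual cost table
#'
#' One row per event x timing x service x stratum, mirroring the published
#' excess-cost table: recycled-prediction means rounded to ten pounds, with
#' optional percentile bootstrap confidence intervals (resampling population
#' members).
#'
#' @param models model map from [load_published_models()].
#' @param population population as in [recycled_excess()]; members must be
#'   valid for the requested strata.
#' @param strata strata to tabulate.
#' @param services services to tabulate.
#' @param n_bootstrap bootstrap resamples for CIs; 0 disables CIs.
#' @param seed seed for the bootstrap.
#' @param rounded round means (and CI bounds) to ten pounds?
#' @return data.frame with stratum, service, event, timing, mean_gbp, ci_low,
#'   ci_high, n_population, n_bootstrap, seed.
#' @export
excess_table <- function(models, population,
                         strata = cohort_strata(),
                         services = c("primary", "hospital"),
                         n_bootstrap = 0, seed = 1, rounded = TRUE) {
  rows <- list()
  for (stratum in strata) for (service in services)
    for (event in .event_kinds) for (timing in event_timings(event)) {
      mean_gbp <- recycled_excess(models, population, event, timing,
                                  service, stratum)
      ci <- c(low = NA_real_, high = NA_real_)
      if (n_bootstrap > 0) {
        ci <- bootstrap_ci(function(pop)
          recycled_excess(models, pop, event, timing, service, stratum),
          population, n_resamples = n_bootstrap, seed = seed)
      }
      if (rounded) {
        mean_gbp <- round_to_ten(mean_gbp)
        ci <- round_to_ten(ci)
      }
      rows[[length(rows) + 1]] <- data.frame(
        stratum = stratum, service = service, event = event, timing = timing,
        mean_gbp = mean_gbp, ci_low_gbp = ci[["low"]], ci_high_gbp = ci[["high"]],
        rounded = rounded,
        n_population = length(population),
        n_bootstrap = if (n_bootstrap > 0) n_bootstrap else NA_integer_,
        seed = if (n_bootstrap > 0) seed else NA_integer_,
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
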