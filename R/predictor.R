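# Design-row encoding and evaluation of the cost model formulas.
#
# Primary care: annual cost = intercept + sum(coefficient * x) (identity-link
# Poisson model, so coefficients are additive pounds). Hospital care, two
# parts: odds of incurring any cost = intercept_odds * prod(OR_i ^ x_i)
# (evaluated as exp of a log-odds sum), probability = odds / (1 + odds)
# overridden to 1 in annual periods with same-year CRV; conditional cost is an
# additive sum like the primary model; expected cost = probability *
# conditional cost.

# Transform a raw numeric field per the term's declared transform.
apply_transform <- function(x, tr) {
  switch(tr$type,
    linear = (x - (tr$center %||% 0)) / (tr$scale %||% 1),
    log = log(x),
    log_linear = (log(x) - (tr$center %||% 0)) / (tr$scale %||% 1)
  )
}

# Vectorised design matrix over a model frame (data.frame with canonical
# fields, one row per person-year). Columns follow model$terms order.
build_design_matrix <- function(frame, model) {
  n <- nrow(frame)
  cols <- lapply(model$terms, function(t) {
    switch(t$kind,
      intercept = rep(1, n),
      categorical_level = {
        v <- .check_frame_levels(t$field, as.character(frame[[t$field]]))
        as.numeric(v %in% t$levels)
      },
      continuous = apply_transform(as.numeric(frame[[t$field]]), t$transform),
      interaction = {
        ind <- rep(1, n)
        for (cc in t$components) {
          v <- .check_frame_levels(cc$field, as.character(frame[[cc$field]]))
          ind <- ind * as.numeric(v %in% cc$levels)
        }
        ind
      }
    )
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(model$terms, `[[`, "", "name")
  X
}

# TRUE where a certainty rule fires for the rows of a frame.
certainty_fires <- function(frame, model) {
  out <- rep(FALSE, nrow(frame))
  for (r in model$certainty_rules)
    out <- out | (as.character(frame[[r$field]]) %in% r$levels)
  out
}

#' Encode a (profile, state) pair as a design row
#'
#' Evaluates every model term at the given covariate profile and annual event
#' state: continuous terms are centred/scaled as declared, categorical terms
#' become 0/1 indicators against the reference, and interaction terms are
#' products of their component indicators. For the reference individual with no
#' events all non-intercept entries are 0.
#'
#' @param profile a [covariate_profile()].
#' @param state an [annual_event_state()].
#' @param model a `coefficient_set`.
#' @return Named numeric vector in term order, with attribute
#'   `certain_positive` (TRUE when a certainty rule, e.g. same-year CRV in the
#'   hospital part-1 model, forces the probability of incurring cost to 1).
#' @export
encode_design_row <- function(profile, state, model) {
  vals <- model_frame_row(profile, state)
  encode_frame_values(vals, model)
}

# Scalar fast path over a named list of frame values.
encode_frame_values <- function(vals, model) {
  for (f in names(vals))
    if (!is.null(.categorical_fields[[f]]))
      vals[[f]] <- .check_frame_levels(f, vals[[f]])
  row <- vapply(model$terms, function(t) {
    switch(t$kind,
      intercept = 1,
      categorical_level = as.numeric(vals[[t$field]] %in% t$levels),
      continuous = apply_transform(as.numeric(vals[[t$field]]), t$transform),
      interaction = {
        v <- 1
        for (cc in t$components)
          v <- v * as.numeric(vals[[cc$field]] %in% cc$levels)
        v
      }
    )
  }, numeric(1))
  names(row) <- vapply(model$terms, `[[`, "", "name")
  certain <- FALSE
  for (r in model$certainty_rules)
    certain <- certain || (vals[[r$field]] %in% r$levels)
  attr(row, "certain_positive") <- certain
  row
}

#' Predict annual primary care cost from a design row
#'
#' @param row design row from [encode_design_row()].
#' @param model the primary-care `coefficient_set` matching the row.
#' @return Annual cost in 2020 GBP. Negative linear predictors (possible under
#'   the identity link) are floored at 0 and flagged via attribute `flags`.
#' @export
predict_primary_cost <- function(row, model) {
  if (model$service != "primary") stop("model service must be 'primary'")
  lp <- sum(vapply(model$terms, `[[`, 0, "coefficient") * as.numeric(row))
  flags <- character(0)
  if (lp < 0) {
    flags <- "negative_linear_predictor_floored"
    lp <- 0
  }
  structure(lp, flags = flags)
}

#' Predict annual hospital cost from the two-part model
#'
#' Part 1 gives the odds of incurring any hospital cost in the year (odds =
#' intercept odds times the product of odds ratios raised to the design-row
#' values, computed as a log-odds sum); the probability is odds/(1+odds),
#' overridden to exactly 1 in annual periods with same-year coronary
#' revascularization. Part 2 gives the cost conditional on incurring any.
#'
#' @param row1,row2 design rows for the part-1 and part-2 models.
#' @param part1,part2 the matching `coefficient_set`s (same stratum).
#' @return List of class `cost_prediction`: `hospital_probability`,
#'   `hospital_conditional_gbp`, `hospital_gbp` (= probability x conditional)
#'   and `flags`.
#' @export
predict_hospital_cost <- function(row1, part1, row2, part2) {
  if (part1$service != "hospital_part1" || part2$service != "hospital_part2")
    stop("models must be hospital_part1 and hospital_part2")
  if (part1$stratum != part2$stratum)
    stop("part 1 and part 2 must share a stratum")
  flags <- character(0)
  eta <- sum(vapply(part1$terms, `[[`, 0, "coefficient") * as.numeric(row1))
  odds <- exp(eta)
  if (!is.finite(odds)) stop("non-finite odds from part-1 model")
  p <- odds / (1 + odds)
  if (isTRUE(attr(row1, "certain_positive"))) {
    p <- 1
    flags <- c(flags, "certainty_rule_applied")
  }
  cond <- sum(vapply(part2$terms, `[[`, 0, "coefficient") * as.numeric(row2))
  if (cond < 0) {
    flags <- c(flags, "negative_conditional_cost_floored")
    cond <- 0
  }
  structure(list(hospital_probability = p,
                 hospital_conditional_gbp = cond,
                 hospital_gbp = p * cond,
                 flags = flags),
            class = "cost_prediction")
}

#' Predict annual costs for one person-year
#'
#' Convenience wrapper: encodes the design rows and evaluates the one-part
#' primary care model and the two-part hospital model for the profile's
#' stratum.
#'
#' @param profile a [covariate_profile()].
#' @param state an [annual_event_state()].
#' @param models model map from [load_published_models()].
#' @param stratum cohort stratum; defaults to the one implied by the profile's
#'   prior CVD history.
#' @return List of class `cost_prediction` with `primary_gbp`,
#'   `hospital_probability`, `hospital_conditional_gbp`, `hospital_gbp`,
#'   `flags`.
#' @export
predict_costs <- function(profile, state, models, stratum = NULL) {
  if (is.null(stratum))
    stratum <- if (profile$prior_cvd_category == "none") "without_cvd" else "with_cvd"
  validate_profile(profile, stratum)
  pm <- models[[paste0(stratum, ".primary")]]
  p1 <- models[[paste0(stratum, ".hospital_part1")]]
  p2 <- models[[paste0(stratum, ".hospital_part2")]]
  if (is.null(pm) || is.null(p1) || is.null(p2))
    stop("model map lacks the three services for stratum ", stratum)
  primary <- predict_primary_cost(encode_design_row(profile, state, pm), pm)
  hosp <- predict_hospital_cost(encode_design_row(profile, state, p1), p1,
                                encode_design_row(profile, state, p2), p2)
  structure(list(primary_gbp = as.numeric(primary),
                 hospital_probability = hosp$hospital_probability,
                 hospital_conditional_gbp = hosp$hospital_conditional_gbp,
                 hospital_gbp = hosp$hospital_gbp,
                 flags = c(attr(primary, "flags"), hosp$flags)),
            class = "cost_prediction")
}

#' @export
print.cost_prediction <- function(x, ...) {
  cat(sprintf(paste0("<cost_prediction>%s hospital: p=%.4f x GBP %.2f",
                     " = GBP %.2f%s\n"),
              if (!is.null(x$primary_gbp))
                sprintf(" primary: GBP %.2f;", x$primary_gbp) else "",
              x$hospital_probability, x$hospital_conditional_gbp,
              x$hospital_gbp,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Predict an annual cost trajectory
#'
#' Advances age and the duration-since-event categories over annual periods
#' anchored at study entry and predicts each year's costs. Death (vascular or
#' non-vascular) is absorbing: the death year is the last annual period in the
#' output.
#'
#' @param profile a [covariate_profile()].
#' @param event_first_years named list of first-occurrence year indices (names
#'   among mi, stroke, crv, diabetes, cancer, vd, nvd).
#' @param horizon_years number of annual periods from entry (>= 1).
#' @param models model map from [load_published_models()].
#' @param stratum optional stratum override.
#' @return data.frame with one row per annual period: year_index, current_age,
#'   primary_gbp, hospital_probability, hospital_conditional_gbp, hospital_gbp,
#'   flags (";"-joined).
#' @export
predict_trajectory <- function(profile, event_first_years = list(),
                               horizon_years, models, stratum = NULL) {
  if (horizon_years < 1) stop("horizon_years must be >= 1")
  death_years <- c(event_first_years$vd, event_first_years$nvd)
  death_years <- death_years[!is.na(death_years)]
  death_year <- if (length(death_years)) min(death_years) else NA_integer_
  if (!is.na(death_year)) {
    if (death_year > horizon_years - 1)
      stop("death year (if any) must fall within the horizon")
    for (nm in c("mi", "stroke", "crv", "diabetes", "cancer")) {
      y <- event_first_years[[nm]]
      if (!is.null(y) && !is.na(y) && y > death_year)
        stop("event '", nm, "' occurs after the death year")
    }
  }
  last <- if (is.na(death_year)) horizon_years - 1 else death_year
  rows <- lapply(0:last, function(y) {
    st <- event_state(profile, event_first_years, y)
    pr <- predict_costs(profile, st, models, stratum)
    data.frame(year_index = y, current_age = st$current_age_years,
               primary_gbp = pr$primary_gbp,
               hospital_probability = pr$hospital_probability,
               hospital_conditional_gbp = pr$hospital_conditional_gbp,
               hospital_gbp = pr$hospital_gbp,
               flags = paste(pr$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
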