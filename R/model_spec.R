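# Loading, validation and serialisation of coefficient sets.
#
# A coefficient set is the machine-readable form of one published (or fitted)
# cost model: an ordered list of terms, each mapping model-frame fields to a
# design-row entry, with its published estimate. Part-1 (logistic) estimates
# are stored as printed odds/odds ratios; the working coefficient is their
# natural log. Cost-model estimates are additive 2020 UK pounds.

.services <- c("primary", "hospital_part1", "hospital_part2")

#' Paths to the shipped published-model fixtures
#'
#' @return Character vector with one JSON fixture per cohort stratum.
#' @export
published_model_paths <- function() {
  c(system.file("extdata", "published_models_2020_without_cvd.json",
                package = "cvdcost", mustWork = TRUE),
    system.file("extdata", "published_models_2020_with_cvd.json",
                package = "cvdcost", mustWork = TRUE))
}

#' Load published (or fitted) cost models from structured-text fixtures
#'
#' Reads one or more JSON fixtures, validates them against the schema, resolves
#' temporal categories merged during model selection (which carry the
#' coefficient of the preceding category of the same event) and returns the
#' coefficient sets keyed `"<stratum>.<service>"`.
#'
#' @param fixture_path character vector of fixture paths; defaults to the two
#'   shipped files (one per stratum).
#' @return Named list of `coefficient_set` objects, e.g.
#'   `models[["without_cvd.primary"]]`.
#' @export
load_published_models <- function(fixture_path = published_model_paths()) {
  models <- list()
  for (path in fixture_path) {
    if (!file.exists(path)) stop("fixture file not found: ", path)
    raw <- jsonlite::read_json(path)
    if (is.null(raw$schema_version) || is.null(raw$models))
      stop("fixture schema violation: missing schema_version or models: ", path)
    for (m in raw$models) {
      cs <- new_coefficient_set(m, price_year = raw$price_year %||% 2020,
                                schema_version = raw$schema_version)
      key <- paste(cs$stratum, cs$service, sep = ".")
      if (!is.null(models[[key]]))
        stop("duplicate model in fixtures: ", key)
      models[[key]] <- cs
    }
  }
  models
}

# Internal constructor + validator for one model entry.
new_coefficient_set <- function(m, price_year = 2020, schema_version = "1.0") {
  for (req in c("stratum", "service", "scale", "terms"))
    if (is.null(m[[req]])) stop("fixture schema violation: model missing ", req)
  stratum <- match.arg(m$stratum, cohort_strata())
  service <- match.arg(m$service, .services)
  scale <- match.arg(m$scale, c("additive_gbp", "log_odds"))
  if (service == "hospital_part1" && scale != "log_odds")
    stop("hospital_part1 must have scale log_odds")
  if (service != "hospital_part1" && scale != "additive_gbp")
    stop(service, " must have scale additive_gbp")

  terms <- lapply(m$terms, validate_term)
  nms <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate term '", nms[duplicated(nms)][1], "' in ",
         stratum, ".", service)
  if (sum(vapply(terms, function(t) t$kind == "intercept", logical(1))) != 1)
    stop("model ", stratum, ".", service, " must have exactly one intercept")
  if (terms[[1]]$kind != "intercept")
    stop("intercept must be the first term in ", stratum, ".", service)

  # Resolve merged temporal categories: coefficient of the nearest preceding
  # non-merged term for the same event.
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    if (!isTRUE(t$merged_with_preceding)) next
    if (is.null(t$event))
      stop("merged term '", t$name, "' has no event tag")
    src <- NULL
    for (j in rev(seq_len(i - 1))) {
      p <- terms[[j]]
      if (identical(p$event, t$event) && !isTRUE(p$merged_with_preceding)) {
        src <- p
        break
      }
    }
    if (is.null(src))
      stop("merged term '", t$name, "' has no preceding category to inherit from")
    terms[[i]]$estimate <- src$estimate
    terms[[i]]$merged_from <- src$name
  }

  # Working coefficient: log of the printed odds/OR for the logistic part,
  # the printed additive pounds otherwise.
  for (i in seq_along(terms)) {
    est <- terms[[i]]$estimate
    if (!is.finite(est)) stop("non-finite estimate for term ", terms[[i]]$name)
    if (scale == "log_odds" && est <= 0)
      stop("odds/odds ratio must be positive for term ", terms[[i]]$name)
    terms[[i]]$coefficient <- if (scale == "log_odds") log(est) else est
  }

  # No dangling fields.
  known <- c(names(.categorical_fields), .numeric_fields)
  for (t in terms) {
    for (f in term_fields(t))
      if (!f %in% known)
        stop("term '", t$name, "' references unknown field '", f, "'")
    if (t$kind == "categorical_level") {
      bad <- setdiff(unlist(t$levels), .categorical_fields[[t$field]])
      if (length(bad))
        stop("term '", t$name, "' uses unknown level '", bad[1],
             "' of field '", t$field, "'")
    }
  }

  rules <- lapply(m$certainty_rules %||% list(), function(r) {
    if (is.null(r$when$field) || is.null(r$when$levels) ||
        is.null(r$probability))
      stop("malformed certainty rule")
    list(field = r$when$field, levels = unlist(r$when$levels),
         probability = as.numeric(r$probability))
  })

  structure(
    list(stratum = stratum, service = service, scale = scale, terms = terms,
         certainty_rules = rules, price_year = price_year,
         schema_version = schema_version),
    class = "coefficient_set"
  )
}

validate_term <- function(t) {
  for (req in c("name", "kind"))
    if (is.null(t[[req]])) stop("fixture schema violation: term missing ", req)
  t$kind <- match.arg(t$kind, c("intercept", "categorical_level",
                                "continuous", "interaction"))
  t$merged_with_preceding <- isTRUE(t$merged_with_preceding)
  if (is.null(t$estimate) && !t$merged_with_preceding)
    stop("term '", t$name, "' has no estimate and is not merged")
  if (!is.null(t$estimate)) t$estimate <- as.numeric(t$estimate)
  if (!is.null(t$se)) t$se <- as.numeric(t$se)
  switch(t$kind,
    categorical_level = {
      if (is.null(t$field) || is.null(t$levels) || !length(t$levels))
        stop("categorical term '", t$name, "' needs field and levels")
      t$levels <- unlist(t$levels)
    },
    continuous = {
      if (is.null(t$field) || is.null(t$transform$type))
        stop("continuous term '", t$name, "' needs field and transform")
      t$transform$type <- match.arg(t$transform$type,
                                    c("linear", "log", "log_linear"))
    },
    interaction = {
      if (is.null(t$components) || length(t$components) < 2)
        stop("interaction term '", t$name, "' needs >= 2 components")
      t$components <- lapply(t$components, function(cc) {
        if (is.null(cc$field) || is.null(cc$levels))
          stop("interaction component of '", t$name, "' needs field and levels")
        list(field = cc$field, levels = unlist(cc$levels))
      })
    },
    intercept = NULL
  )
  t
}

# Fields a term reads from the model frame.
term_fields <- function(t) {
  switch(t$kind,
    intercept = character(0),
    categorical_level = ,
    continuous = t$field,
    interaction = vapply(t$components, `[[`, "", "field")
  )
}

#' Serialise coefficient sets back to a fixture file
#'
#' Inverse of [load_published_models()]: writes the printed estimates (not the
#' derived log-odds) so a round trip reproduces the fixture's numbers exactly.
#'
#' @param models named list of `coefficient_set` objects (one stratum).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "coefficient_set")) models <- list(models)
  entries <- lapply(models, function(cs) {
    terms <- lapply(cs$terms, function(t) {
      out <- t[intersect(names(t),
                         c("name", "label", "kind", "field", "levels",
                           "transform", "components", "event", "timing",
                           "se", "merged_with_preceding"))]
      out$estimate <- if (isTRUE(t$merged_with_preceding)) NULL else t$estimate
      out$levels <- if (!is.null(t$levels)) as.list(t$levels) else NULL
      if (!is.null(t$components))
        out$components <- lapply(t$components, function(cc)
          list(field = cc$field, levels = as.list(cc$levels)))
      out
    })
    list(stratum = cs$stratum, service = cs$service, scale = cs$scale,
         certainty_rules = lapply(cs$certainty_rules, function(r)
           list(when = list(field = r$field, levels = as.list(r$levels)),
                probability = r$probability)),
         terms = terms)
  })
  doc <- list(schema_version = models[[1]]$schema_version %||% "1.0",
              currency = "GBP", price_year = models[[1]]$price_year,
              models = unname(entries))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Validate a covariate profile against a cohort stratum
#'
#' Checks stratum/history consistency and flags out-of-range biomarkers.
#' The input is never modified.
#'
#' @param profile a [covariate_profile()].
#' @param stratum "without_cvd" or "with_cvd".
#' @return Character vector of warnings (empty if none). Inconsistent
#'   stratum/history and non-positive HDL or creatinine are hard errors.
#' @export
validate_profile <- function(profile, stratum = c("without_cvd", "with_cvd")) {
  stratum <- match.arg(stratum)
  if (!inherits(profile, "covariate_profile"))
    stop("profile must be a covariate_profile")
  if (stratum == "with_cvd" && profile$prior_cvd_category == "none")
    stop("with_cvd stratum requires prior_cvd_category != 'none'")
  if (stratum == "without_cvd" && profile$prior_cvd_category != "none")
    stop("without_cvd stratum requires prior_cvd_category == 'none'")
  if (profile$hdl_mmol_per_l <= 0)
    stop("hdl_mmol_per_l must be strictly positive (its natural log is taken)")
  if (profile$creatinine_umol_per_l <= 0)
    stop("creatinine_umol_per_l must be strictly positive")

  w <- character(0)
  rng <- function(value, lo, hi, what, unit) {
    if (value < lo || value > hi)
      sprintf("%s = %g %s outside plausible range [%g, %g]",
              what, value, unit, lo, hi)
    else character(0)
  }
  w <- c(w,
    rng(profile$ldl_mmol_per_l, 0.5, 15, "LDL cholesterol", "mmol/L"),
    rng(profile$hdl_mmol_per_l, 0.3, 5, "HDL cholesterol", "mmol/L"),
    rng(profile$creatinine_umol_per_l, 20, 1000, "creatinine", "umol/L"),
    rng(profile$sbp_mmhg, 70, 250, "systolic blood pressure", "mmHg"),
    rng(profile$dbp_mmhg, 40, 150, "diastolic blood pressure", "mmHg"))
  if (profile$dbp_mmhg >= profile$sbp_mmhg)
    w <- c(w, "diastolic blood pressure >= systolic blood pressure")
  if (profile$ethnicity == "missing")
    w <- c(w, "ethnicity 'missing' carries no model coefficient; it is treated as the reference (white) at prediction time")
  if (profile$prior_type1_diabetes && profile$prior_type2_diabetes)
    w <- c(w, "both type 1 and type 2 prior diabetes flagged; type 1 term will be applied")
  w
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s / %s (%s, %d terms, price year %d)\n",
              x$stratum, x$service, x$scale, length(x$terms), x$price_year))
  invisible(x)
}

#' Term estimates of a coefficient set as a data frame
#'
#' @param model a `coefficient_set`.
#' @return data.frame with name, kind, estimate (as printed), working
#'   coefficient, SE and merge provenance.
#' @export
coefficients_table <- function(model) {
  data.frame(
    name = vapply(model$terms, `[[`, "", "name"),
    kind = vapply(model$terms, `[[`, "", "kind"),
    estimate = vapply(model$terms, function(t) t$estimate, numeric(1)),
    coefficient = vapply(model$terms, function(t) t$coefficient, numeric(1)),
    se = vapply(model$terms, function(t) t$se %||% NA_real_, numeric(1)),
    merged_with_preceding = vapply(model$terms, function(t)
      isTRUE(t$merged_with_preceding), logical(1)),
    stringsAsFactors = FALSE
  )
}
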