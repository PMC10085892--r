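# Quasi-likelihood GLM estimation for person-year cost panels.
#
# Families are specified through their variance function only (quasi
# likelihood), so the identity-link "Poisson" model is valid for continuous
# costs: coefficients are additive pounds and the variance is assumed
# proportional to the mean. Identity-link Poisson/Gamma fits guard against
# non-positive fitted means by step-halving. Standard errors are one-way
# cluster-robust sandwich estimates grouped by participant with a G/(G-1)
# small-sample factor.

.fam_variance <- function(family) {
  switch(family,
    gaussian = function(mu) rep(1, length(mu)),
    poisson = function(mu) mu,
    gamma = function(mu) mu^2,
    binomial = function(mu) mu * (1 - mu)
  )
}

.link_funs <- function(link) {
  switch(link,
    identity = list(linkinv = identity, mu_eta = function(eta) rep(1, length(eta))),
    log = list(linkinv = exp, mu_eta = exp),
    logit = list(linkinv = stats::plogis,
                 mu_eta = function(eta) stats::plogis(eta) * (1 - stats::plogis(eta)))
  )
}

.mu_valid <- function(mu, family) {
  switch(family,
    gaussian = all(is.finite(mu)),
    poisson = , gamma = all(is.finite(mu)) && all(mu > 0),
    binomial = all(is.finite(mu)) && all(mu > 0 & mu < 1)
  )
}

.deviance <- function(y, mu, family) {
  switch(family,
    gaussian = sum((y - mu)^2),
    poisson = {
      t1 <- ifelse(y > 0, y * log(y / mu), 0)
      2 * sum(t1 - (y - mu))
    },
    gamma = 2 * sum(-log(y / mu) + (y - mu) / mu),
    binomial = {
      t1 <- ifelse(y > 0, y * log(y / mu), 0)
      t0 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
      2 * sum(t1 + t0)
    }
  )
}

# IRLS with step-halving; X must include the intercept column.
glm_irls <- function(X, y, family = c("gaussian", "poisson", "gamma", "binomial"),
                     link = c("identity", "log", "logit"),
                     maxit = 100, tol = 1e-9) {
  family <- match.arg(family)
  link <- match.arg(link)
  V <- .fam_variance(family)
  lk <- .link_funs(link)
  n <- nrow(X)
  p <- ncol(X)
  if (family %in% c("poisson", "binomial") && any(y < 0))
    stop("responses must be non-negative")
  if (family == "gamma" && any(y <= 0))
    stop("gamma family requires strictly positive responses")

  # Starting values: intercept-only fit in the valid mean domain.
  beta <- numeric(p)
  ybar <- mean(y)
  beta[1] <- switch(link,
    identity = if (family %in% c("poisson", "gamma")) max(ybar, 1e-6) else ybar,
    log = log(max(ybar, 1e-6)),
    logit = stats::qlogis(min(max(ybar, 1e-4), 1 - 1e-4))
  )
  eta <- drop(X %*% beta)
  mu <- lk$linkinv(eta)
  dev <- .deviance(y, mu, family)
  converged <- FALSE

  for (it in seq_len(maxit)) {
    m <- lk$mu_eta(eta)
    w <- m^2 / V(mu)
    if (any(!is.finite(w)) || any(w <= 0)) w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / m
    fit <- stats::lm.wfit(X, z, w)
    if (any(is.na(fit$coefficients))) {
      bad <- colnames(X)[is.na(fit$coefficients)]
      stop("singular design; collinear terms: ", paste(bad, collapse = ", "))
    }
    beta_new <- fit$coefficients
    # step-halving until the mean is in the valid domain and the deviance is
    # finite and non-increasing (allowing a small tolerance)
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_c <- drop(X %*% cand)
      mu_c <- lk$linkinv(eta_c)
      if (.mu_valid(mu_c, family)) {
        dev_c <- .deviance(y, mu_c, family)
        if (is.finite(dev_c) && dev_c <= dev * (1 + 1e-8)) break
      }
      step <- step / 2
      if (step < 1e-10) {
        dev_c <- dev
        cand <- beta
        eta_c <- eta
        mu_c <- mu
        break
      }
    }
    delta <- max(abs(cand - beta)) / max(1, max(abs(cand)))
    beta <- cand
    eta <- eta_c
    mu <- mu_c
    if (abs(dev - dev_c) / (abs(dev_c) + 0.1) < tol || delta < tol) {
      dev <- dev_c
      converged <- TRUE
      break
    }
    dev <- dev_c
  }
  m <- lk$mu_eta(eta)
  w <- m^2 / V(mu)
  list(coefficients = stats::setNames(beta, colnames(X)),
       fitted = mu, eta = eta, weights = w,
       score_resid = (y - mu) * m / V(mu),
       deviance = dev, converged = converged, family = family, link = link,
       n = n, p = p)
}

# One-way cluster-robust sandwich covariance with G/(G-1) factor.
cluster_vcov <- function(X, fit, cluster) {
  A <- crossprod(X * sqrt(fit$weights))
  s <- X * fit$score_resid
  Sg <- rowsum(s, group = cluster)
  G <- nrow(Sg)
  meat <- crossprod(as.matrix(Sg))
  Ainv <- solve(A)
  vc <- Ainv %*% meat %*% Ainv * G / max(1, G - 1)
  dimnames(vc) <- list(colnames(X), colnames(X))
  vc
}

# Accept a coefficient_set, a list with $terms, or a bare term list.
.term_list <- function(terms) {
  if (inherits(terms, "coefficient_set") || !is.null(terms$terms)) terms$terms
  else terms
}

#' Term constructors for custom model specifications
#'
#' Build term lists for [fit_glm()] and [stepwise_select()] over arbitrary
#' panel columns (the published fixtures carry their own terms).
#'
#' @param name term name.
#' @param field panel column.
#' @param levels character levels activating the indicator.
#' @param center,scale linear transform `(x - center)/scale`.
#' @param components list of `list(field=, levels=)` component indicators.
#' @param block optional selection-block label (defaults to the field); terms
#'   sharing a block enter and leave stepwise selection together.
#' @return A term object (list).
#' @name term-constructors
#' @export
term_intercept <- function() {
  list(name = "intercept", kind = "intercept", merged_with_preceding = FALSE)
}

#' @rdname term-constructors
#' @export
term_continuous <- function(name, field, center = 0, scale = 1, block = field) {
  list(name = name, kind = "continuous", field = field,
       transform = list(type = "linear", center = center, scale = scale),
       block = block, merged_with_preceding = FALSE)
}

#' @rdname term-constructors
#' @export
term_level <- function(name, field, levels, block = field) {
  list(name = name, kind = "categorical_level", field = field, levels = levels,
       block = block, merged_with_preceding = FALSE)
}

#' @rdname term-constructors
#' @export
term_interaction <- function(name, components, block = name) {
  list(name = name, kind = "interaction",
       components = lapply(components, function(cc)
         list(field = cc$field %||% cc[[1]], levels = cc$levels %||% cc[[2]])),
       block = block, merged_with_preceding = FALSE)
}

# Selection block of a term (categorical covariates move as blocks).
.term_block <- function(t) {
  if (!is.null(t$block)) t$block
  else if (t$kind == "interaction")
    paste(vapply(t$components, `[[`, "", "field"), collapse = ":")
  else t$field %||% t$name
}

.design_for <- function(panel, terms) {
  tl <- .term_list(terms)
  X <- build_design_matrix(panel, list(terms = tl))
  X
}

#' Fit a GLM to a person-year cost panel
#'
#' Quasi-likelihood IRLS fit with cluster-robust standard errors grouped by
#' participant. The identity-link Poisson variant is the published primary care
#' / hospital part-2 model form. Person-years flagged `primary_excluded`
#' (registration gaps) are dropped automatically when the response is
#' `primary_gbp`.
#'
#' @param panel person-year panel (data.frame with canonical model-frame
#'   columns).
#' @param response name of the response column (e.g. "primary_gbp",
#'   "hospital_gbp").
#' @param family "gaussian", "poisson", "gamma" or "binomial" (variance
#'   function; fitting is quasi-likelihood so continuous responses are fine).
#' @param link "identity", "log" or "logit".
#' @param terms a `coefficient_set` or list of terms defining the design
#'   (see [term-constructors]); the intercept must be included.
#' @param cluster_field panel column identifying the participant.
#' @param subset optional logical vector of rows to use.
#' @return Object of class `cvdcost_fit`: coefficients, cluster_robust_se,
#'   vcov, dispersion, fitted values, convergence flag and diagnostics (AIC
#'   or quasi-AIC, RMSE, MAE, predicted-observed correlation, modified Park
#'   test slope; Hosmer-Lemeshow statistic for logistic fits).
#' @export
fit_glm <- function(panel, response, family = "poisson", link = "identity",
                    terms, cluster_field = "person_id", subset = NULL) {
  if (!is.null(subset)) panel <- panel[subset, , drop = FALSE]
  # person-years with primary care registration gaps never enter primary fits
  if (response == "primary_gbp" && !is.null(panel$primary_excluded))
    panel <- panel[!panel$primary_excluded, , drop = FALSE]
  y <- as.numeric(panel[[response]])
  if (is.null(y)) stop("response column '", response, "' not found")
  X <- .design_for(panel, terms)
  cl <- panel[[cluster_field]]
  if (length(unique(cl)) < 2) stop("need >= 2 clusters for cluster-robust SEs")
  fit <- glm_irls(X, y, family = family, link = link)
  vc <- cluster_vcov(X, fit, cl)
  se <- sqrt(diag(vc))
  disp <- sum((y - fit$fitted)^2 / .fam_variance(family)(fit$fitted)) /
    (fit$n - fit$p)
  mu <- fit$fitted
  res <- y - mu
  ok <- mu > 0 & res^2 > 0
  park <- if (sum(ok) > 10 && family != "binomial") {
    stats::coef(stats::lm(log(res[ok]^2) ~ log(mu[ok])))[2]
  } else NA_real_
  aic <- switch(family,
    gaussian = {
      s2 <- mean(res^2)
      fit$n * log(2 * pi * s2) + fit$n + 2 * (fit$p + 1)
    },
    binomial = .deviance(y, mu, "binomial") + 2 * fit$p,
    # quasi-families: quasi-AIC = Pearson-scaled deviance + 2 p
    fit$deviance / max(disp, 1e-12) + 2 * fit$p
  )
  hl <- if (family == "binomial") hosmer_lemeshow(y, mu)$statistic else NA_real_
  structure(list(
    coefficients = fit$coefficients,
    cluster_robust_se = stats::setNames(se, names(fit$coefficients)),
    vcov = vc, family = family, link = link,
    n_obs = fit$n, n_clusters = length(unique(cl)),
    converged = fit$converged, dispersion = disp,
    deviance = fit$deviance, fitted = mu, response = response,
    terms = .term_list(terms), cluster_field = cluster_field,
    diagnostics = list(aic = unname(aic),
                       rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
                       cor_pred_obs = if (stats::sd(mu) > 0)
                         stats::cor(mu, y) else NA_real_,
                       park_slope = unname(park),
                       hosmer_lemeshow = unname(hl))
  ), class = "cvdcost_fit")
}

#' @export
print.cvdcost_fit <- function(x, ...) {
  cat(sprintf("<cvdcost_fit> %s/%s, n=%d (%d clusters), %s\n",
              x$family, x$link, x$n_obs, x$n_clusters,
              if (x$converged) "converged" else "NOT CONVERGED"))
  tab <- data.frame(coefficient = x$coefficients, se = x$cluster_robust_se)
  print(utils::head(tab, 15))
  if (nrow(tab) > 15) cat("... (", nrow(tab) - 15, " more terms)\n", sep = "")
  invisible(x)
}

# Hosmer-Lemeshow goodness of fit on fitted probabilities.
hosmer_lemeshow <- function(y, p, groups = 10) {
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  g <- cut(p, breaks = br, include.lowest = TRUE)
  O <- tapply(y, g, sum)
  E <- tapply(p, g, sum)
  n_g <- tapply(y, g, length)
  pbar <- E / n_g
  stat <- sum((O - E)^2 / pmax(n_g * pbar * (1 - pbar), 1e-12))
  df <- length(O) - 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fit the two-part hospital cost model
#'
#' Part 1: logistic regression for the probability of incurring any hospital
#' cost; part 2: GLM for the cost conditional on incurring any, fitted to the
#' rows with positive costs. Annual periods with same-year CRV are excluded
#' from part 1 (incurring cost is certain there, mirroring the published
#' models' certainty rule) but retained in part 2.
#'
#' @param panel person-year panel with a `hospital_any` indicator column.
#' @param terms1,terms2 term specifications for the two parts.
#' @param part2_family,part2_link part-2 family/link (published form:
#'   poisson/identity).
#' @param cluster_field participant id column.
#' @param response part-2 response column.
#' @param crv_certainty exclude same-year-CRV rows from part 1?
#' @return List of class `cvdcost_two_part`: `logistic` and `conditional` fits
#'   plus `flags`.
#' @export
fit_two_part <- function(panel, terms1, terms2,
                         part2_family = "poisson", part2_link = "identity",
                         cluster_field = "person_id",
                         response = "hospital_gbp",
                         crv_certainty = TRUE) {
  if (is.null(panel$hospital_any)) stop("panel lacks a hospital_any column")
  flags <- character(0)
  part1_rows <- if (crv_certainty && !is.null(panel$crv))
    panel$crv != "same_year" else rep(TRUE, nrow(panel))
  y1 <- panel$hospital_any[part1_rows]
  if (length(unique(y1)) < 2) {
    flags <- c(flags, "part1_separation_degenerate")
    logistic <- NULL
  } else {
    p1 <- panel[part1_rows, , drop = FALSE]
    p1$.any <- as.numeric(p1$hospital_any)
    logistic <- fit_glm(p1, ".any", family = "binomial", link = "logit",
                        terms = terms1, cluster_field = cluster_field)
    if (any(logistic$fitted > 1 - 1e-8) || any(logistic$fitted < 1e-8))
      flags <- c(flags, "part1_near_separation")
  }
  pos <- panel$hospital_any == 1
  if (!any(pos)) stop("part 2 sample is empty (no person-years with costs)")
  conditional <- fit_glm(panel[pos, , drop = FALSE], response,
                         family = part2_family, link = part2_link,
                         terms = terms2, cluster_field = cluster_field)
  structure(list(logistic = logistic, conditional = conditional,
                 flags = flags),
            class = "cvdcost_two_part")
}

#' Predict from a fitted two-part model
#'
#' Combines the fitted parts with the published prediction formula
#' (probability x conditional cost), applying the same-year-CRV certainty rule
#' when part 1 was fitted without those rows.
#'
#' @param fit a `cvdcost_two_part`.
#' @param panel person-year rows to predict for.
#' @param crv_certainty apply the same-year-CRV certainty override?
#' @return data.frame with probability, conditional and expected cost.
#' @export
predict_two_part <- function(fit, panel, crv_certainty = TRUE) {
  p <- if (is.null(fit$logistic)) rep(1, nrow(panel)) else {
    X1 <- .design_for(panel, fit$logistic$terms)
    stats::plogis(drop(X1 %*% fit$logistic$coefficients))
  }
  if (crv_certainty && !is.null(panel$crv)) p[panel$crv == "same_year"] <- 1
  X2 <- .design_for(panel, fit$conditional$terms)
  lk <- .link_funs(fit$conditional$link)
  cond <- lk$linkinv(drop(X2 %*% fit$conditional$coefficients))
  data.frame(hospital_probability = p, hospital_conditional_gbp = cond,
             hospital_gbp = p * cond)
}

#' Compare candidate GLM family/link pairs
#'
#' Fits each of the candidate family/link pairs, computes in-sample AIC (or
#' quasi-AIC) and the modified Park-test slope, and cross-validates RMSE/MAE
#' and the predicted-observed correlation with folds split by participant.
#' Candidates are ranked by Park-test consistency (slope closest to the
#' family's variance power: gaussian 0, poisson 1, gamma 2), ties broken by
#' cross-validated RMSE, then by parsimony (identity before log link).
#'
#' @param panel person-year panel.
#' @param response response column.
#' @param terms design specification.
#' @param candidates data.frame with family/link columns (default: all six).
#' @param k_folds number of CV folds (>= 2), split by cluster.
#' @param cluster_field participant id column.
#' @param seed fold-assignment seed.
#' @return data.frame of diagnostics, ranked (best first); non-converging or
#'   inapplicable candidates are excluded with a notice.
#' @export
compare_candidates <- function(panel, response, terms,
                               candidates = expand.grid(
                                 family = c("gaussian", "poisson", "gamma"),
                                 link = c("identity", "log"),
                                 stringsAsFactors = FALSE),
                               k_folds = 5, cluster_field = "person_id",
                               seed = 1) {
  if (k_folds < 2) stop("k_folds must be >= 2")
  ids <- unique(panel[[cluster_field]])
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k_folds), length(ids))))
  names(fold_of) <- as.character(ids)
  fold <- fold_of[as.character(panel[[cluster_field]])]
  y <- as.numeric(panel[[response]])
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    fam <- candidates$family[i]
    lnk <- candidates$link[i]
    res <- tryCatch({
      full <- fit_glm(panel, response, family = fam, link = lnk, terms = terms,
                      cluster_field = cluster_field)
      pred <- rep(NA_real_, nrow(panel))
      for (k in seq_len(k_folds)) {
        tr <- fold != k
        fit_k <- fit_glm(panel, response, family = fam, link = lnk,
                         terms = terms, cluster_field = cluster_field,
                         subset = tr)
        Xk <- .design_for(panel[!tr, , drop = FALSE], terms)
        lk <- .link_funs(lnk)
        pred[!tr] <- lk$linkinv(drop(Xk %*% fit_k$coefficients))
      }
      if (!full$converged) stop("did not converge")
      data.frame(family = fam, link = lnk,
                 aic = full$diagnostics$aic,
                 park_slope = full$diagnostics$park_slope,
                 cv_rmse = sqrt(mean((y - pred)^2)),
                 cv_mae = mean(abs(y - pred)),
                 cv_cor = stats::cor(pred, y),
                 converged = full$converged,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("candidate ", fam, "/", lnk, " excluded: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("no candidate converged")
  out <- do.call(rbind, rows)
  target <- c(gaussian = 0, poisson = 1, gamma = 2)[out$family]
  out$park_gap <- abs(out$park_slope - target)
  out <- out[order(out$park_gap, out$cv_rmse, out$link != "identity"), ]
  rownames(out) <- NULL
  out
}

#' Bidirectional stepwise covariate selection at a fixed significance level
#'
#' Backward elimination with forward re-inclusion using cluster-robust Wald
#' tests on selection blocks (all levels of a categorical covariate move
#' together; the intercept is never dropped). At each step the included block
#' with the largest p-value >= alpha is dropped; otherwise the excluded block
#' with the smallest p-value < alpha is re-added. Ties are broken by canonical
#' term order, making runs deterministic.
#'
#' @param panel person-year panel.
#' @param response response column.
#' @param full_terms full term list (including the intercept).
#' @param alpha significance level (published models: 0.01).
#' @param family,link GLM family/link.
#' @param cluster_field participant id column.
#' @return List of class `cvdcost_selection`: `trace` (data.frame step, action,
#'   block, p_value), `terms` (final term list) and `fit` (final model).
#' @export
stepwise_select <- function(panel, response, full_terms, alpha = 0.01,
                            family = "poisson", link = "identity",
                            cluster_field = "person_id") {
  tl <- .term_list(full_terms)
  blocks <- vapply(tl, .term_block, "")
  blocks[vapply(tl, function(t) t$kind == "intercept", TRUE)] <- ".intercept"
  block_order <- unique(blocks[blocks != ".intercept"])
  included <- block_order
  trace <- list()
  step <- 0L
  seen <- character(0)

  fit_for <- function(incl) {
    keep <- blocks == ".intercept" | blocks %in% incl
    fit_glm(panel, response, family = family, link = link, terms = tl[keep],
            cluster_field = cluster_field)
  }
  block_p <- function(fit, block) {
    nm <- vapply(fit$terms, `[[`, "", "name")
    bl <- vapply(fit$terms, .term_block, "")
    idx <- which(bl == block)
    b <- fit$coefficients[idx]
    Vb <- fit$vcov[idx, idx, drop = FALSE]
    W <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) Inf)
    stats::pchisq(W, df = length(idx), lower.tail = FALSE)
  }

  repeat {
    state <- paste(sort(included), collapse = "|")
    if (state %in% seen || step > 100) break
    seen <- c(seen, state)
    fit <- fit_for(included)
    acted <- FALSE
    if (length(included)) {
      pv <- vapply(included, function(b) block_p(fit, b), 0)
      if (any(pv >= alpha)) {
        worst <- included[order(-pv, match(included, block_order))][1]
        step <- step + 1L
        trace[[step]] <- data.frame(step = step, action = "drop",
                                    block = worst, p_value = pv[[worst]],
                                    stringsAsFactors = FALSE)
        included <- setdiff(included, worst)
        acted <- TRUE
      }
    }
    if (!acted) {
      excluded <- setdiff(block_order, included)
      if (length(excluded)) {
        pv <- vapply(excluded, function(b) {
          f2 <- fit_for(c(included, b))
          block_p(f2, b)
        }, 0)
        if (any(pv < alpha)) {
          best <- excluded[order(pv, match(excluded, block_order))][1]
          step <- step + 1L
          trace[[step]] <- data.frame(step = step, action = "add",
                                      block = best, p_value = pv[[best]],
                                      stringsAsFactors = FALSE)
          included <- union(included, best)
          acted <- TRUE
        }
      }
    }
    if (!acted) break
  }
  final_fit <- fit_for(included)
  structure(list(
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(0), action = character(0),
                 block = character(0), p_value = numeric(0)),
    included_blocks = included,
    terms = tl[blocks == ".intercept" | blocks %in% included],
    fit = final_fit
  ), class = "cvdcost_selection")
}
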