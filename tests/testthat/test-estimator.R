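# GLM fitting, cluster-robust inference, two-part fitting, model comparison
# and stepwise selection.

# small synthetic panel over generic covariates
toy_panel <- function(n, beta0 = 100, beta_x = 50, sd = 10, seed = 1,
                      years = 1) {
  set.seed(seed)
  person <- rep(seq_len(n), each = years)
  x <- rep(rnorm(n), each = years)
  z <- rep(rnorm(n), each = years)
  mu <- beta0 + beta_x * x
  data.frame(person_id = person, x = x, z = z,
             y = mu + rnorm(n * years, sd = sd))
}

toy_terms <- list(term_intercept(),
                  term_continuous("x", "x"),
                  term_continuous("z", "z"))

test_that("gaussian/identity on noiseless linear data recovers coefficients exactly", {
  set.seed(2)
  df <- data.frame(person_id = 1:200, x = rnorm(200), z = rnorm(200))
  df$y <- 3 + 2 * df$x - 5 * df$z
  fit <- fit_glm(df, "y", "gaussian", "identity", terms = toy_terms)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(3, 2, -5), tolerance = 1e-8)
})

test_that("IRLS agrees with stats::glm across families and links", {
  set.seed(3)
  n <- 800
  df <- data.frame(person_id = 1:n, x = runif(n, 0, 2), z = rnorm(n))
  mu <- 5 + 3 * df$x + 0 * df$z
  df$y <- rgamma(n, shape = 2, scale = mu / 2)
  for (spec in list(c("poisson", "identity"), c("gamma", "identity"),
                    c("poisson", "log"), c("gamma", "log"),
                    c("gaussian", "log"))) {
    fit <- fit_glm(df, "y", spec[1], spec[2], terms = toy_terms)
    fam <- switch(spec[1],
                  poisson = stats::quasipoisson(link = spec[2]),
                  gamma = stats::Gamma(link = spec[2]),
                  gaussian = stats::gaussian(link = spec[2]))
    ref <- suppressWarnings(stats::glm(
      y ~ x + z, data = df, family = fam,
      start = unname(fit$coefficients)))
    expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
                 tolerance = 1e-5, label = paste(spec, collapse = "/"))
  }
  # logistic
  df$b <- as.integer(runif(n) < stats::plogis(-1 + 1.5 * df$x))
  fitb <- fit_glm(df, "b", "binomial", "logit", terms = toy_terms)
  refb <- stats::glm(b ~ x + z, data = df, family = stats::binomial())
  expect_equal(unname(fitb$coefficients), unname(stats::coef(refb)),
               tolerance = 1e-6)
})

test_that("identity-link Poisson guards against non-positive means via step-halving", {
  # data where the OLS start would put some fitted means negative
  set.seed(4)
  n <- 400
  df <- data.frame(person_id = 1:n, x = c(rep(0, n - 5), rep(1, 5)),
                   z = rnorm(n))
  df$y <- rgamma(n, 1, scale = pmax(0.5, 1 + 9 * df$x))
  fit <- fit_glm(df, "y", "poisson", "identity", terms = toy_terms)
  expect_true(fit$converged)
  expect_true(all(fit$fitted > 0))
})

test_that("singular designs fail with the collinear term named", {
  df <- toy_panel(100)
  df$x2 <- df$x
  terms <- c(toy_terms, list(term_continuous("x_copy", "x2")))
  expect_error(fit_glm(df, "y", "gaussian", "identity", terms = terms),
               "singular design.*x_copy")
})

test_that("with one observation per cluster, sandwich SEs match the jackknife", {
  set.seed(5)
  n <- 300
  df <- data.frame(person_id = 1:n, x = rnorm(n), z = rnorm(n))
  df$y <- 2 + 3 * df$x + rnorm(n, sd = abs(df$x) + 0.5)   # heteroscedastic
  fit <- fit_glm(df, "y", "gaussian", "identity", terms = toy_terms)
  # brute-force delete-one jackknife SE
  X <- cbind(1, df$x, df$z)
  betas <- t(vapply(seq_len(n), function(i) {
    stats::coef(stats::lm.fit(X[-i, ], df$y[-i]))
  }, numeric(3)))
  jack <- sqrt((n - 1) / n * colSums(scale(betas, scale = FALSE)^2))
  expect_equal(unname(fit$cluster_robust_se), unname(jack), tolerance = 0.05)
})

test_that("clustered data inflate SEs relative to ignoring the clustering", {
  set.seed(6)
  n <- 150
  years <- 4
  u <- rnorm(n, sd = 20)                       # person random effect
  df <- data.frame(person_id = rep(1:n, each = years),
                   x = rep(rnorm(n), each = years))
  df$z <- rnorm(n * years)
  df$y <- 100 + 10 * df$x + rep(u, each = years) + rnorm(n * years, sd = 5)
  fit_cl <- fit_glm(df, "y", "gaussian", "identity", terms = toy_terms)
  df2 <- df
  df2$person_id <- seq_len(nrow(df2))          # pretend independence
  fit_iid <- fit_glm(df2, "y", "gaussian", "identity", terms = toy_terms)
  expect_gt(fit_cl$cluster_robust_se[["x"]], 1.5 * fit_iid$cluster_robust_se[["x"]])
  expect_identical(fit_cl$n_clusters, as.integer(n))
})

test_that("parameter recovery: refitting a simulated panel recovers the truth", {
  m <- models_all()
  cfg <- simulation_config(
    n_participants = 4000, horizon_years = 5, stratum_mix = 0,
    hazards = list(mi = 0.02, stroke = 0.02, crv = 0.03, diabetes = 0.02,
                   cancer = 0.04, vd = 0.01, nvd = 0.015),
    seed = 31)
  panel <- suppressWarnings(simulate_panel(m, cfg))
  pm <- m[["without_cvd.primary"]]
  fit <- suppressWarnings(   # 'missing' ethnicity maps to reference, warned
    fit_glm(panel, "primary_gbp", "poisson", "identity", terms = pm))
  expect_true(fit$converged)
  truth <- vapply(pm$terms, `[[`, 0, "coefficient")
  z <- (fit$coefficients - truth) / fit$cluster_robust_se
  expect_gte(mean(abs(z) < 3), 0.95)
})

test_that("two-part fitting recovers both parts and matches the predictor", {
  m <- models_all()
  cfg <- simulation_config(
    n_participants = 4000, horizon_years = 5, stratum_mix = 0,
    hazards = list(mi = 0.02, stroke = 0.02, crv = 0.03, diabetes = 0.02,
                   cancer = 0.04, vd = 0.01, nvd = 0.015),
    seed = 32)
  panel <- suppressWarnings(simulate_panel(m, cfg))
  p1 <- m[["without_cvd.hospital_part1"]]
  p2 <- m[["without_cvd.hospital_part2"]]
  tp <- suppressWarnings(fit_two_part(panel, terms1 = p1, terms2 = p2))
  expect_true(tp$logistic$converged)
  expect_true(tp$conditional$converged)
  z1 <- (tp$logistic$coefficients - vapply(p1$terms, `[[`, 0, "coefficient")) /
    tp$logistic$cluster_robust_se
  z2 <- (tp$conditional$coefficients - vapply(p2$terms, `[[`, 0, "coefficient")) /
    tp$conditional$cluster_robust_se
  expect_gte(mean(abs(c(z1, z2)) < 3), 0.95)
  # MI same-year log-OR specifically (the headline coefficient)
  expect_lt(abs(z1[["mi_same_year"]]), 3)
  # combined prediction equals probability x conditional on the same rows
  pred <- predict_two_part(tp, panel[1:50, ])
  expect_equal(pred$hospital_gbp,
               pred$hospital_probability * pred$hospital_conditional_gbp)
  expect_identical(pred$hospital_probability[panel$crv[1:50] == "same_year"],
                   rep(1, sum(panel$crv[1:50] == "same_year")))
})

test_that("an all-positive-cost panel flags part-1 separation and degenerates", {
  df <- toy_panel(120, seed = 9)
  df$hospital_any <- 1L
  df$hospital_gbp <- abs(df$y)
  tp <- fit_two_part(df, terms1 = toy_terms, terms2 = toy_terms)
  expect_true("part1_separation_degenerate" %in% tp$flags)
  expect_null(tp$logistic)
  one_part <- fit_glm(df, "hospital_gbp", "poisson", "identity",
                      terms = toy_terms)
  expect_equal(tp$conditional$coefficients, one_part$coefficients)
  pred <- predict_two_part(tp, df[1:5, ])
  expect_identical(pred$hospital_probability, rep(1, 5))
})

test_that("the Park-test slope identifies the variance law", {
  set.seed(12)
  n <- 6000
  df <- data.frame(person_id = 1:n, x = runif(n, 0, 3), z = rnorm(n))
  mu <- 5 + 10 * df$x
  # variance proportional to the mean (Poisson-like): gamma(shape=mu, scale=1)
  df$y <- rgamma(n, shape = mu, scale = 1)
  fit1 <- fit_glm(df, "y", "poisson", "identity", terms = toy_terms)
  expect_lt(abs(fit1$diagnostics$park_slope - 1), 0.35)
  # constant variance (gaussian law)
  df$y <- mu + rnorm(n, sd = 2)
  fit0 <- fit_glm(df, "y", "gaussian", "identity", terms = toy_terms)
  expect_lt(abs(fit0$diagnostics$park_slope - 0), 0.35)
  # variance proportional to mean^2 (gamma law)
  df$y <- rgamma(n, shape = 4, scale = mu / 4)
  fit2 <- fit_glm(df, "y", "gamma", "identity", terms = toy_terms)
  expect_lt(abs(fit2$diagnostics$park_slope - 2), 0.35)
})

test_that("compare_candidates ranks the generative family first", {
  set.seed(13)
  n <- 4000
  df <- data.frame(person_id = 1:n, x = runif(n, 0, 3), z = rnorm(n))
  mu <- 5 + 10 * df$x
  df$y <- rgamma(n, shape = mu, scale = 1)        # variance = mean
  tab <- compare_candidates(df, "y", toy_terms, k_folds = 3, seed = 1)
  expect_identical(tab$family[1], "poisson")
  expect_identical(tab$link[1], "identity")
  expect_true(all(c("aic", "park_slope", "cv_rmse", "cv_mae", "cv_cor")
                  %in% names(tab)))
  # identical candidates produce identical diagnostics
  tab2 <- compare_candidates(df, "y", toy_terms,
                             candidates = data.frame(
                               family = c("poisson", "poisson"),
                               link = c("identity", "identity"),
                               stringsAsFactors = FALSE),
                             k_folds = 3, seed = 1)
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
})

test_that("stepwise selection drops noise, keeps signal, moves blocks together", {
  set.seed(17)
  n <- 600
  df <- data.frame(person_id = 1:n, x = rnorm(n), z = rnorm(n),
                   g = sample(c("a", "b", "c"), n, replace = TRUE))
  df$y <- 100 + 40 * df$x + 30 * (df$g == "b") + 60 * (df$g == "c") +
    rnorm(n, sd = 10)
  terms <- list(term_intercept(),
                term_continuous("x", "x"),
                term_continuous("z", "z"),
                term_level("g_b", "g", "b", block = "g"),
                term_level("g_c", "g", "c", block = "g"))
  sel <- stepwise_select(df, "y", terms, alpha = 0.01,
                         family = "gaussian", link = "identity")
  expect_setequal(sel$included_blocks, c("x", "g"))
  expect_true(all(sel$trace$action[sel$trace$block == "z"] == "drop"))
  # dropped blocks had p >= alpha at their drop step
  expect_true(all(sel$trace$p_value[sel$trace$action == "drop"] >= 0.01))
  # block rule: both g levels present in the final terms
  nms <- vapply(sel$terms, `[[`, "", "name")
  expect_true(all(c("g_b", "g_c") %in% nms))
  # alpha = 1 returns the full model
  sel_full <- stepwise_select(df, "y", terms, alpha = 1,
                              family = "gaussian", link = "identity")
  expect_setequal(sel_full$included_blocks, c("x", "z", "g"))
})

test_that("stepwise error rates behave across replicates", {
  set.seed(15)
  n <- 300
  keep_strong <- logical(20)
  drop_noise <- logical(20)
  for (r in 1:20) {
    df <- data.frame(person_id = 1:n, x = rnorm(n), z = rnorm(n))
    df$y <- 100 + 30 * df$x + rnorm(n, sd = 10)
    sel <- stepwise_select(df, "y", toy_terms, alpha = 0.01,
                           family = "gaussian", link = "identity")
    keep_strong[r] <- "x" %in% sel$included_blocks
    drop_noise[r] <- !("z" %in% sel$included_blocks)
  }
  expect_identical(mean(keep_strong), 1)
  expect_gte(mean(drop_noise), 0.9)
})
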