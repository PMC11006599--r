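test_that("with no group structure the LMM reduces to ordinary least squares", {
  d <- grouped_data(10, 6, seed = 21)
  d$y <- 1.5 + 0.8 * d$x + rnorm(nrow(d), 0, 0.5)  # no group effect
  fit <- suppressMessages(suppressWarnings(
    fit_lmm(d, response = "y", fixed = "x", random = "(1 | g)")))
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fixed_effects(fit)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("balanced one-way variance components match the ANOVA closed form", {
  set.seed(33)
  d <- grouped_data(6, 5, seed = 33)
  d$y <- 2 + rnorm(6, 0, 1.2)[as.integer(d$g)] + rnorm(nrow(d), 0, 0.6)
  fit <- fit_lmm(d, response = "y", fixed = "1", random = "(1 | g)")
  oracle <- anova_varcomp_oracle(d$y, d$g)
  expect_equal(unname(ranef_variances(fit)[["g"]]), oracle$var_between,
               tolerance = 1e-6)
  expect_equal(stats::sigma(fit$fit)^2, oracle$var_within, tolerance = 1e-6)
})

test_that("Wald chi-square for a single-coefficient term is (beta/SE)^2", {
  study <- simulate_study(seed = 5)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  fit <- suppressMessages(suppressWarnings(fit_lmm(tab)))
  an <- wald_anova(fit)
  beta <- fixed_effects(fit)
  V <- as.matrix(vcov(fit$fit))
  term <- "risk_c:cropoilseed_rape:cropland_c"
  z2 <- (beta[[term]] / sqrt(V[term, term]))^2
  expect_equal(an$chisq[an$term == "risk_c:crop:cropland_c"], z2,
               tolerance = 1e-8)
  expect_equal(an$p[an$term == "risk_c:crop:cropland_c"],
               pchisq(z2, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(all(an$df == 1))
})

test_that("variance-partition R2 matches hand bookkeeping; conditional >= marginal", {
  study <- simulate_study(seed = 9)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  fit <- suppressMessages(suppressWarnings(fit_lmm(tab)))
  r2 <- r2_nakagawa(fit)
  X <- model.matrix(fit$fit)
  vf <- var(as.numeric(X %*% fixed_effects(fit)))
  vr <- sum(ranef_variances(fit))
  ve <- sigma(fit$fit)^2
  expect_equal(r2$marginal, vf / (vf + vr + ve), tolerance = 1e-10)
  expect_equal(r2$conditional, (vf + vr) / (vf + vr + ve), tolerance = 1e-10)
  expect_gte(r2$conditional, r2$marginal)
  # intercept-only fixed part: marginal R2 is exactly 0
  fit0 <- suppressMessages(suppressWarnings(
    fit_lmm(tab, fixed = "1")))
  expect_equal(r2_nakagawa(fit0)$marginal, 0, tolerance = 1e-12)
  fitnb <- suppressWarnings(fit_nb_glmm(tab))
  r2nb <- r2_nakagawa(fitnb)
  expect_gte(r2nb$conditional, r2nb$marginal)
  expect_true(r2nb$marginal > 0 && r2nb$conditional < 1)
})

test_that("simple slopes equal a refit on the shifted moderator", {
  study <- simulate_study(seed = 12)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  fit <- suppressMessages(suppressWarnings(fit_lmm(tab)))
  s <- sd(tab$cropland_c)
  sl <- simple_slopes(fit, cropland_c = c(plus_sd = s))
  # reparameterization oracle: shift the moderator so "+1 SD" becomes 0
  tab2 <- tab
  tab2$cropland_c <- tab2$cropland_c - s
  fit2 <- suppressMessages(suppressWarnings(fit_lmm(tab2)))
  beta2 <- fixed_effects(fit2)
  expect_equal(sl$slope[sl$crop == "apple"], beta2[["risk_c"]],
               tolerance = 1e-6)
  expect_equal(sl$slope[sl$crop == "oilseed_rape"],
               beta2[["risk_c"]] + beta2[["risk_c:cropoilseed_rape"]],
               tolerance = 1e-6)
  # without interactions the slope is flat across moderators
  fit0 <- suppressMessages(suppressWarnings(
    fit_lmm(tab, fixed = "g_initial_c + risk_c + crop + cropland_c")))
  sl0 <- simple_slopes(fit0, cropland_c = c(-0.2, 0, 0.2))
  expect_equal(length(unique(round(sl0$slope, 12))), 1L)
})

test_that("the NB GLMM with fixed huge dispersion matches Poisson regression", {
  set.seed(41)
  d <- grouped_data(8, 8, seed = 41)
  d$y <- rpois(nrow(d), exp(2 + 0.4 * d$x))
  fit <- suppressWarnings(fit_nb_glmm(d, response = "y", fixed = "x",
                                      random = "(1 | g)", fix_theta = 1e8))
  oracle <- glm(y ~ x, poisson, data = d)
  expect_equal(unname(fixed_effects(fit)), unname(coef(oracle)),
               tolerance = 1e-4)
})

test_that("the ZINB with zero inflation pinned at 0 equals the plain NB fit", {
  set.seed(43)
  d <- grouped_data(8, 8, seed = 43)
  u <- rnorm(8, 0, 0.3)
  d$y <- rnbinom(nrow(d), mu = exp(2 + 0.3 * d$x + u[as.integer(d$g)]),
                 size = 4)
  nb <- suppressWarnings(fit_nb_glmm(d, response = "y", fixed = "x",
                                     random = "(1 | g)"))
  zi <- suppressWarnings(fit_zinb_glmm(d, response = "y", fixed = "x",
                                       random = "(1 | g)", fix_zi_prob = 0))
  expect_equal(zi_prob(zi), 0, tolerance = 1e-10)
  expect_equal(fixed_effects(zi), fixed_effects(nb), tolerance = 1e-4)
  expect_equal(nb_theta(zi), nb_theta(nb), tolerance = 1e-3)
  expect_equal(as.numeric(logLik(zi$fit)), as.numeric(logLik(nb$fit)),
               tolerance = 1e-6)
  # free pi on data without excess zeros collapses toward 0
  zfree <- suppressWarnings(fit_zinb_glmm(d, response = "y", fixed = "x",
                                          random = "(1 | g)"))
  expect_lt(zi_prob(zfree), 0.05)
})

test_that("dispersion ratio calibrates at 1 for Poisson data and flags NB data", {
  set.seed(47)
  d <- grouped_data(30, 10, seed = 47)
  d$y <- rpois(nrow(d), exp(2 + 0.3 * d$x))
  fp <- suppressWarnings(fit_poisson_glmm(d, response = "y", fixed = "x",
                                          random = "(1 | g)"))
  expect_equal(diagnostics(fp)$dispersion_ratio, 1, tolerance = 0.2)
  d$y2 <- rnbinom(nrow(d), mu = exp(4 + 0.3 * d$x), size = 2)
  fp2 <- suppressWarnings(fit_poisson_glmm(d, response = "y2", fixed = "x",
                                           random = "(1 | g)"))
  expect_gt(diagnostics(fp2)$dispersion_ratio, 5)
})

test_that("VIF is exactly 1 on an orthogonal design and finite on the study design", {
  d <- grouped_data(10, 8, seed = 53)
  n <- nrow(d)
  d$x1 <- rep(c(-1, 1), n / 2)
  d$x2 <- rep(c(-1, -1, 1, 1), n / 4)
  d$y <- rnorm(n)
  fit <- suppressMessages(suppressWarnings(
    fit_lmm(d, response = "y", fixed = "x1 + x2", random = "(1 | g)")))
  expect_equal(unname(diagnostics(fit)$vif), c(1, 1), tolerance = 1e-10)
  study <- simulate_study(seed = 3)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  v <- diagnostics(suppressMessages(suppressWarnings(fit_lmm(tab))))$vif
  expect_true(all(v >= 1) && all(v < 10))
})

test_that("the covariate independence check separates related from unrelated pairs", {
  set.seed(59)
  country <- rep(LETTERS[1:8], each = 13)
  x <- rnorm(104)
  ic <- suppressWarnings(independence_check(x, x, country))
  expect_gt(ic$r2_marginal, 0.99)
  ic2 <- independence_check(x, rnorm(104), country)
  expect_lt(ic2$r2_marginal, 0.1)
  expect_warning(independence_check(x, rnorm(104), rep("A", 104)),
                 "fewer than 2")
})

test_that("marginal means back-transform and reproduce the coefficient algebra", {
  set.seed(61)
  d <- grouped_data(12, 8, seed = 61)
  d$risk_c <- rnorm(nrow(d))
  u <- rnorm(12, 0, 0.2)
  d$y <- rnbinom(nrow(d), mu = exp(3 - 0.4 * d$risk_c + u[as.integer(d$g)]),
                 size = 5)
  fit <- suppressWarnings(fit_nb_glmm(d, response = "y", fixed = "risk_c",
                                      random = "(1 | g)"))
  rc <- risk_contrast(fit)
  beta <- fixed_effects(fit)[["risk_c"]]
  dq <- diff(quantile(d$risk_c, c(0.25, 0.90), names = FALSE))
  # algebraic oracle: the ratio of marginal means is exp(beta * delta)
  expect_equal(rc$means[2] / rc$means[1], exp(beta * dq), tolerance = 1e-6)
  expect_equal(rc$reduction, 1 - exp(beta * dq), tolerance = 1e-6)
  # intercept-only Gaussian model: the marginal mean is the grand mean
  d$z <- 5 + u[as.integer(d$g)] + rnorm(nrow(d), 0, 0.1)
  f0 <- suppressMessages(suppressWarnings(
    fit_lmm(d, response = "z", fixed = "1", random = "(1 | g)")))
  mm <- marginal_means(f0)
  expect_equal(mm$mean, unname(fixed_effects(f0)[1]), tolerance = 1e-8)
})

test_that("fit summaries serialize to JSON and restore numerically", {
  study <- simulate_study(seed = 15)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  fit <- suppressWarnings(fit_zinb_glmm(tab))
  s <- fit_summary(fit)
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(s, p, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$coefficients$risk_c, s$coefficients$risk_c)
  expect_equal(back$theta, s$theta)
  expect_equal(back$zi_prob, s$zi_prob)
  expect_equal(back$n, nrow(tab))
})
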