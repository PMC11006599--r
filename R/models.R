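#' Hierarchical models for colony performance
#'
#' Four models link colony performance to mixture risk, focal crop and
#' landscape cropland, each with initial colony weight as a covariate,
#' all two-way interactions among risk/crop/cropland plus the three-way
#' interaction as fixed effects, and random intercepts for site nested in
#' country:
#' * weight gain (lnRR): Gaussian LMM (REML);
#' * total production: negative binomial (NB2) GLMM, log link, ML via the
#'   Laplace approximation;
#' * maximum weight: Gaussian LMM on the log scale (untransformed option);
#' * queen production: zero-inflated NB GLMM with a single constant
#'   zero-inflation probability.
#'
#' LMMs are fitted with \pkg{lme4}, count GLMMs with \pkg{glmmTMB}; term
#' tests are Type II Wald chi-square.
#'
#' @name mixed_models
NULL

.default_fixed <- "g_initial_c + risk_c * crop * cropland_c"
.default_random <- "(1 | country / site_id)"

.compose_formula <- function(response, fixed, random) {
  stats::as.formula(paste(response, "~", fixed, "+", random))
}

.new_colony_fit <- function(fit, family, response, data, formula,
                            log_response = FALSE) {
  conv <- if (inherits(fit, "glmmTMB")) {
    isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  } else {
    length(fit@optinfo$conv$lme4$messages) == 0L &&
      isTRUE(fit@optinfo$conv$opt == 0)
  }
  if (!conv) warning("model fit did not converge cleanly", call. = FALSE)
  structure(
    list(fit = fit, family = family, response = response, data = data,
         formula = formula, log_response = log_response, converged = conv),
    class = "colony_fit")
}

#' @export
print.colony_fit <- function(x, ...) {
  cat("<colony_fit> ", x$family, " model for '", x$response, "'",
      if (x$log_response) " (log scale)", "\n", sep = "")
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat("  converged: ", x$converged, "; logLik = ",
      round(as.numeric(stats::logLik(x$fit)), 2), "\n", sep = "")
  invisible(x)
}

#' Fit the Gaussian linear mixed model
#'
#' @param data An `analysis_table` (or any data frame with the referenced
#'   columns).
#' @param response Response column, default `"lnrr"` (weight gain); use
#'   `"g_max"` with `log_response = TRUE` for the maximum-weight model.
#' @param fixed Right-hand side of the fixed-effects formula (string).
#' @param random Random-effects term (string); default site nested in
#'   country.
#' @param reml Use REML (default) or ML.
#' @param log_response Model `log(response)` instead of the raw response.
#' @return A `colony_fit` wrapping the \pkg{lme4} fit.
#' @export
fit_lmm <- function(data, response = "lnrr", fixed = .default_fixed,
                    random = .default_random, reml = TRUE,
                    log_response = FALSE) {
  resp <- response
  if (log_response) {
    if (any(data[[response]] <= 0)) {
      stop("log transform needs a strictly positive response", call. = FALSE)
    }
    resp <- paste0(".log_", response)
    data[[resp]] <- log(data[[response]])
  }
  form <- .compose_formula(resp, fixed, random)
  fit <- lme4::lmer(form, data = data, REML = reml)
  .new_colony_fit(fit, "gaussian", response, data, form, log_response)
}

#' Fit the negative binomial GLMM
#'
#' NB2 parameterization (variance mu + mu^2 / theta), log link, maximum
#' likelihood via the Laplace approximation.
#'
#' @inheritParams fit_lmm
#' @param response Count response column, default `"total_production"`.
#' @param ziformula Zero-inflation formula; `~0` (none) here, `~1` for the
#'   zero-inflated variant.
#' @param fix_theta Optionally hold the NB dispersion fixed at this value
#'   instead of estimating it (a very large value gives the Poisson limit).
#' @param fix_zi_prob Optionally hold the zero-inflation probability fixed
#'   (0 gives the plain NB limit of the zero-inflated model).
#' @return A `colony_fit` wrapping the \pkg{glmmTMB} fit; the estimated
#'   dispersion is `nb_theta()` of the result. A very large theta (Poisson
#'   boundary) triggers a warning.
#' @export
fit_nb_glmm <- function(data, response = "total_production",
                        fixed = .default_fixed, random = .default_random,
                        ziformula = ~0, fix_theta = NULL, fix_zi_prob = NULL) {
  if (any(data[[response]] < 0)) stop("counts must be nonnegative", call. = FALSE)
  form <- .compose_formula(response, fixed, random)
  start <- list(); map <- list()
  if (!is.null(fix_theta)) {
    start$betad <- log(fix_theta)
    map$betad <- factor(NA)
  }
  if (!is.null(fix_zi_prob)) {
    if (identical(ziformula, ~0)) ziformula <- ~1
    # clamp: logit(0) is -Inf, -30 is numerically indistinguishable
    start$betazi <- max(stats::qlogis(fix_zi_prob), -30)
    map$betazi <- factor(NA)
  }
  fit <- glmmTMB::glmmTMB(form, data = data, family = glmmTMB::nbinom2(),
                          ziformula = ziformula, start = start, map = map)
  theta <- glmmTMB::sigma(fit)
  if (is.finite(theta) && theta > 1e6) {
    warning("NB dispersion at the Poisson boundary (theta > 1e6)",
            call. = FALSE)
  }
  fam <- if (identical(ziformula, ~0)) "negative_binomial" else
    "zi_negative_binomial"
  .new_colony_fit(fit, fam, response, data, form)
}

#' Fit the zero-inflated negative binomial GLMM
#'
#' The queen-production model: a point mass of structural zeros with a
#' single constant mixing probability pi (intercept-only on the logit
#' scale) on top of the NB2 count model of [fit_nb_glmm()].
#'
#' @inheritParams fit_nb_glmm
#' @param response Count response column, default `"queen_production"`.
#' @return A `colony_fit`; `zi_prob()` extracts the estimated pi.
#' @export
fit_zinb_glmm <- function(data, response = "queen_production",
                          fixed = .default_fixed, random = .default_random,
                          fix_zi_prob = NULL) {
  fit_nb_glmm(data, response = response, fixed = fixed, random = random,
              ziformula = ~1, fix_zi_prob = fix_zi_prob)
}

#' Poisson GLMM (overdispersion reference fit)
#'
#' Used by [diagnostics()] to demonstrate overdispersion of the count
#' responses relative to a Poisson error.
#'
#' @inheritParams fit_nb_glmm
#' @return A `colony_fit` with family `"poisson"`.
#' @export
fit_poisson_glmm <- function(data, response = "total_production",
                             fixed = .default_fixed,
                             random = .default_random) {
  form <- .compose_formula(response, fixed, random)
  fit <- glmmTMB::glmmTMB(form, data = data, family = stats::poisson())
  .new_colony_fit(fit, "poisson", response, data, form)
}

#' Fixed-effect coefficients of a colony fit
#' @param object A `colony_fit`.
#' @return Named numeric vector (conditional-model coefficients for count
#'   fits).
#' @export
fixed_effects <- function(object) {
  if (inherits(object$fit, "glmmTMB")) glmmTMB::fixef(object$fit)$cond
  else lme4::fixef(object$fit)
}

.fixed_vcov <- function(object) {
  if (inherits(object$fit, "glmmTMB")) stats::vcov(object$fit)$cond
  else as.matrix(stats::vcov(object$fit))
}

#' Random-intercept variances of a colony fit
#' @param object A `colony_fit`.
#' @return Named numeric vector of random-intercept variances.
#' @export
ranef_variances <- function(object) {
  vc <- if (inherits(object$fit, "glmmTMB")) {
    glmmTMB::VarCorr(object$fit)$cond
  } else {
    lme4::VarCorr(object$fit)
  }
  out <- vapply(vc, function(m) m[1, 1], 0)
  names(out) <- names(vc)
  out
}

#' NB dispersion of a count fit
#' @param object A `colony_fit` with an NB family.
#' @return The NB2 dispersion theta.
#' @export
nb_theta <- function(object) {
  stopifnot(inherits(object$fit, "glmmTMB"))
  glmmTMB::sigma(object$fit)
}

#' Zero-inflation probability of a ZINB fit
#' @param object A `colony_fit` from [fit_zinb_glmm()].
#' @return Estimated constant zero-inflation probability pi.
#' @export
zi_prob <- function(object) {
  stopifnot(inherits(object$fit, "glmmTMB"))
  zi <- glmmTMB::fixef(object$fit)$zi
  if (!length(zi)) return(0)
  stats::plogis(zi[["(Intercept)"]])
}

#' Type II Wald chi-square table
#'
#' Per-term Wald chi-square tests (each model term is 1 df here), the
#' inference reported for every model; for a single-coefficient term the
#' statistic is (beta / SE)^2.
#'
#' @param object A converged `colony_fit`.
#' @return Data frame with columns `term`, `chisq`, `df`, `p`.
#' @export
wald_anova <- function(object) {
  a <- car::Anova(object$fit, type = "II")
  out <- data.frame(term = rownames(a),
                    chisq = a[["Chisq"]],
                    df = a[["Df"]],
                    p = a[["Pr(>Chisq)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Marginal and conditional R-squared
#'
#' Variance-partition R2 for mixed models: marginal R2 is the variance of
#' the fixed-effect predictor over the total (fixed + random intercepts +
#' observation-level) variance; conditional R2 adds the random-intercept
#' variances to the numerator. The observation-level variance is the
#' residual variance for Gaussian fits; for NB log-link fits it is the
#' trigamma-based distribution variance `trigamma(1/(1/lambda + 1/theta))`
#' with `lambda = exp(mean(X beta) + 0.5 * sum(random variances))`, falling
#' back to the lognormal approximation `log(1 + 1/lambda + 1/theta)` if the
#' trigamma value is not finite.
#'
#' @param object A converged `colony_fit`.
#' @return Named list with `marginal` and `conditional`.
#' @export
r2_nakagawa <- function(object) {
  beta <- fixed_effects(object)
  X <- .fixed_model_matrix(object)
  var_f <- stats::var(as.numeric(X %*% beta))
  var_r <- sum(ranef_variances(object))
  var_o <- if (object$family == "gaussian") {
    stats::sigma(object$fit)^2
  } else if (object$family == "poisson") {
    lambda <- exp(mean(as.numeric(X %*% beta)) + 0.5 * var_r)
    v <- trigamma(lambda)
    if (!is.finite(v)) log1p(1 / lambda) else v
  } else {
    theta <- nb_theta(object)
    lambda <- exp(mean(as.numeric(X %*% beta)) + 0.5 * var_r)
    nu <- 1 / (1 / lambda + 1 / theta)
    v <- trigamma(nu)
    if (!is.finite(v)) log1p(1 / lambda + 1 / theta) else v
  }
  tot <- var_f + var_r + var_o
  list(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

.fixed_model_matrix <- function(object) {
  if (inherits(object$fit, "glmmTMB")) {
    stats::model.matrix(object$fit)
  } else {
    stats::model.matrix(object$fit, type = "fixed")
  }
}

#' Simple slopes of risk at moderator settings
#'
#' The effect of the (transformed, centred) risk covariate evaluated at
#' each crop and at chosen cropland values, as a linear combination of the
#' interaction coefficients; the CI comes from the delta rule on the
#' coefficient covariance.
#'
#' @param object A `colony_fit` whose fixed part includes
#'   `risk_c * crop * cropland_c`.
#' @param cropland_c Centred cropland values at which to evaluate; the
#'   default evaluates at the mean and at plus/minus one SD of cropland in
#'   the fitted data.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `crop`, `cropland_c`, `slope`, `se`, `lower`,
#'   `upper`.
#' @export
simple_slopes <- function(object, cropland_c = NULL, level = 0.95) {
  beta <- fixed_effects(object)
  V <- .fixed_vcov(object)
  if (!("risk_c" %in% names(beta))) {
    stop("fit has no 'risk_c' term", call. = FALSE)
  }
  if (is.null(cropland_c)) {
    s <- if ("cropland_c" %in% names(object$data))
      stats::sd(object$data$cropland_c) else 0
    cropland_c <- c(mean = 0, plus_sd = s, minus_sd = -s)
  }
  crops <- levels(object$data$crop) %||% c("apple", "oilseed_rape")
  z <- stats::qnorm(1 - (1 - level) / 2)
  pick <- function(nm) if (nm %in% names(beta)) nm else NA_character_
  grid <- expand.grid(crop = crops, cropland_c = cropland_c,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cr <- grid$crop[i]; zl <- grid$cropland_c[i]
    L <- stats::setNames(numeric(length(beta)), names(beta))
    L["risk_c"] <- 1
    nm <- pick(paste0("risk_c:crop", cr))
    if (!is.na(nm)) L[nm] <- 1
    nm <- pick("risk_c:cropland_c")
    if (!is.na(nm)) L[nm] <- zl
    nm <- pick(paste0("risk_c:crop", cr, ":cropland_c"))
    if (!is.na(nm)) L[nm] <- zl
    est <- sum(L * beta)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    data.frame(crop = cr, cropland_c = zl, slope = est, se = se,
               lower = est - z * se, upper = est + z * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marginal means over a reference grid
#'
#' Expected response at chosen covariate settings, averaging over crop
#' levels and holding the remaining covariates at their means (reference
#' grid), back-transformed to the response scale for count models and for
#' log-transformed Gaussian fits. Computed with \pkg{emmeans}.
#'
#' @param object A converged `colony_fit`.
#' @param at Named list of covariate settings, e.g.
#'   `list(risk_c = c(-1, 1))`.
#' @return Data frame of marginal means with confidence limits on the
#'   response scale (`mean`, `lower`, `upper` plus the grid columns).
#' @export
marginal_means <- function(object, at = list()) {
  specs <- if (length(at)) stats::as.formula(paste("~", paste(names(at), collapse = "*")))
  else ~1
  rg_data <- object$data
  for (v in names(at)) {
    if (!v %in% names(rg_data)) stop("unknown covariate '", v, "'", call. = FALSE)
    rng <- range(rg_data[[v]])
    if (any(at[[v]] < rng[1] - 1e-8 | at[[v]] > rng[2] + 1e-8)) {
      warning("marginal means requested outside the observed range of '",
              v, "'", call. = FALSE)
    }
  }
  # averaging over crop inside its interactions is deliberate here
  emm <- suppressMessages(
    emmeans::emmeans(object$fit, specs, at = at,
                     type = "response", data = object$data))
  s <- as.data.frame(summary(emm))
  est_col <- intersect(c("response", "rate", "emmean"), names(s))[1]
  lo_col <- intersect(c("lower.CL", "asymp.LCL"), names(s))[1]
  hi_col <- intersect(c("upper.CL", "asymp.UCL"), names(s))[1]
  s$mean <- s[[est_col]]
  s$lower <- if (!is.na(lo_col)) s[[lo_col]] else NA_real_
  s$upper <- if (!is.na(hi_col)) s[[hi_col]] else NA_real_
  if (object$log_response) {
    s$mean <- exp(s$mean); s$lower <- exp(s$lower); s$upper <- exp(s$upper)
  }
  s[, c(names(at), "mean", "lower", "upper"), drop = FALSE]
}

#' Low- vs high-risk marginal-mean contrast
#'
#' Compares the expected response at a low-risk and a high-risk setting
#' (by default the 25th and 90th percentiles of the fitted risk covariate):
#' the absolute difference and the proportional reduction
#' `1 - mean(high) / mean(low)`.
#'
#' @param object A converged `colony_fit`.
#' @param probs Length-2 probabilities defining the low and high risk
#'   quantiles (default `c(0.25, 0.90)`).
#' @return List with `risk_c` (the two covariate values), `means` (the two
#'   marginal means), `difference` (low minus high) and `reduction`
#'   (proportional).
#' @export
risk_contrast <- function(object, probs = c(0.25, 0.90)) {
  q <- stats::quantile(object$data$risk_c, probs, names = FALSE, type = 7)
  mm <- marginal_means(object, at = list(risk_c = q))
  list(risk_c = q, means = mm$mean,
       difference = mm$mean[1] - mm$mean[2],
       reduction = 1 - mm$mean[2] / mm$mean[1])
}

#' Model diagnostics: dispersion and collinearity
#'
#' The dispersion ratio is the sum of squared Pearson residuals over the
#' residual degrees of freedom (n minus the number of fixed coefficients);
#' computed on a Poisson fit it demonstrates overdispersion, on the NB fit
#' adequacy. VIFs come from the correlation matrix of the fixed-effects
#' design (intercept dropped): the diagonal of its inverse.
#'
#' @param object A converged `colony_fit`.
#' @return List with `dispersion_ratio`, `residual_df` and `vif` (named
#'   vector, one per fixed-effect column).
#' @export
diagnostics <- function(object) {
  pr <- stats::residuals(object$fit, type = "pearson")
  X <- .fixed_model_matrix(object)
  df <- length(pr) - ncol(X)
  disp <- sum(pr^2) / df
  Xn <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  keep <- apply(Xn, 2, stats::sd) > 0
  Xn <- Xn[, keep, drop = FALSE]
  vif <- if (ncol(Xn) >= 2) diag(solve(stats::cor(Xn)))
  else stats::setNames(rep(1, ncol(Xn)), colnames(Xn))
  list(dispersion_ratio = disp, residual_df = df, vif = vif)
}

#' Independence check between two site-level covariates
#'
#' Confirms (or refutes) that two covariates are unrelated once country
#' membership is accounted for: an LMM of `y` on `x` with a country random
#' intercept, reporting the marginal R2 and the Wald chi-square for the
#' slope. With fewer than two countries a plain regression is used with a
#' warning.
#'
#' @param x,y Numeric site-level vectors.
#' @param country Grouping factor.
#' @return List with `r2_marginal`, `chisq`, `p`, `slope`.
#' @export
independence_check <- function(x, y, country) {
  d <- data.frame(x = x, y = y, country = factor(country))
  if (nlevels(d$country) < 2L) {
    warning("fewer than 2 countries: plain regression fallback", call. = FALSE)
    f <- stats::lm(y ~ x, data = d)
    beta <- stats::coef(f)[["x"]]
    se <- sqrt(stats::vcov(f)["x", "x"])
    chisq <- (beta / se)^2
    return(list(r2_marginal = summary(f)$r.squared, chisq = chisq,
                p = stats::pchisq(chisq, 1, lower.tail = FALSE), slope = beta))
  }
  f <- lme4::lmer(y ~ x + (1 | country), data = d, REML = TRUE)
  beta <- lme4::fixef(f)[["x"]]
  # a perfect (zero-residual) fit can make the covariance degenerate
  se <- tryCatch(sqrt(as.matrix(stats::vcov(f))["x", "x"]),
                 error = function(e) NA_real_)
  chisq <- if (is.na(se) || se == 0) Inf else (beta / se)^2
  var_f <- stats::var(as.numeric(stats::model.matrix(f) %*% lme4::fixef(f)))
  vc <- lme4::VarCorr(f)
  var_r <- sum(vapply(vc, function(m) m[1, 1], 0))
  var_e <- attr(vc, "sc")^2
  list(r2_marginal = var_f / (var_f + var_r + var_e),
       chisq = chisq,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       slope = beta)
}

#' Serializable summary of a fit
#'
#' A plain-list snapshot (coefficients, SEs, variance components,
#' dispersion, zero inflation, log-likelihood, convergence, group sizes)
#' suitable for `jsonlite::write_json()` and regression testing.
#'
#' @param object A `colony_fit`.
#' @return Named list of plain vectors.
#' @export
fit_summary <- function(object) {
  beta <- fixed_effects(object)
  se <- sqrt(diag(.fixed_vcov(object)))
  out <- list(
    response = object$response,
    family = object$family,
    coefficients = as.list(beta),
    se = as.list(stats::setNames(se, names(beta))),
    varcomp = as.list(ranef_variances(object)),
    loglik = as.numeric(stats::logLik(object$fit)),
    converged = object$converged,
    n = nrow(object$data))
  if (object$family == "gaussian") out$sigma <- stats::sigma(object$fit)
  if (grepl("negative_binomial", object$family)) out$theta <- nb_theta(object)
  if (object$family == "zi_negative_binomial") out$zi_prob <- zi_prob(object)
  out
}
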