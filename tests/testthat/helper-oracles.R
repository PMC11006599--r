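# Independent numerical oracles. Nothing here calls lme4/glmmTMB or any
# pollenrisk model-fitting code: these exist to cross-check those routes.

# Marginal log-likelihood of a single-random-intercept model by adaptive
# Gauss-Hermite quadrature (default 21 nodes): per group, centre the rule at
# the mode of the integrand and scale by its curvature.
agq_loglik <- function(y, X, group, beta, sd_re, family,
                       sigma = NULL, theta = NULL, pi = 0, nodes = 21) {
  eta <- as.numeric(X %*% beta)
  dens <- switch(family,
    gaussian = function(y, m) stats::dnorm(y, m, sigma, log = TRUE),
    nb = function(y, m) stats::dnbinom(y, mu = exp(m), size = theta,
                                       log = TRUE),
    zinb = function(y, m) log(pi * (y == 0) +
      (1 - pi) * stats::dnbinom(y, mu = exp(m), size = theta)))
  if (sd_re < 1e-8) return(sum(dens(y, eta)))
  gh <- pracma::gaussHermite(nodes)
  total <- 0
  for (g in unique(group)) {
    idx <- group == g
    f <- function(u) sum(dens(y[idx], eta[idx] + u)) +
      stats::dnorm(u, 0, sd_re, log = TRUE)
    mode <- stats::optimize(f, c(-10 * sd_re, 10 * sd_re),
                            maximum = TRUE)$maximum
    h <- 1e-4 * max(abs(mode), sd_re)
    d2 <- -(f(mode + h) - 2 * f(mode) + f(mode - h)) / h^2
    s <- sqrt(2 / d2)
    lw <- log(gh$w) + gh$x^2 + vapply(gh$x, function(x) f(mode + s * x), 0)
    m <- max(lw)
    total <- total + log(s) + m + log(sum(exp(lw - m)))
  }
  total
}

# Method-of-moments variance components for a balanced one-way layout
# (k groups, n replicates each): between/within mean squares.
anova_varcomp_oracle <- function(y, group) {
  k <- length(unique(group))
  n <- length(y) / k
  gm <- tapply(y, group, mean)
  msb <- n * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[group])^2) / (k * (n - 1))
  list(var_between = (msb - msw) / n, var_within = msw)
}

# Direct zero-inflated NB log-likelihood, no random effects: plain sum of
# per-observation mixture densities.
zinb_loglik_direct <- function(y, mu, theta, pi) {
  sum(log(pi * (y == 0) + (1 - pi) * stats::dnbinom(y, mu = mu, size = theta)))
}

# Parameter pullers for the quadrature comparisons.
fitted_params <- function(cf) {
  beta <- fixed_effects(cf)
  vc <- ranef_variances(cf)
  list(beta = beta, sd_re = sqrt(vc[[1]]),
       sigma = if (cf$family == "gaussian") stats::sigma(cf$fit) else NULL,
       theta = if (grepl("negative_binomial", cf$family)) nb_theta(cf) else NULL,
       pi = if (cf$family == "zi_negative_binomial") zi_prob(cf) else 0)
}
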