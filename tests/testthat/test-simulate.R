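test_that("regeneration under the same seed is bit-identical", {
  a <- simulate_study(seed = 4)
  b <- simulate_study(seed = 4)
  expect_identical(a, b)
  c <- simulate_study(seed = 5)
  expect_false(identical(a$colonies, c$colonies))
})

test_that("the default landscape has 106 sites in 8 countries spanning the gradient", {
  set.seed(1)
  sites <- simulate_landscape()
  expect_equal(nrow(sites), 106)
  expect_equal(length(unique(sites$country)), 8)
  expect_equal(sum(sites$crop == "apple"), 50)
  expect_equal(sum(sites$crop == "oilseed_rape"), 56)
  expect_true(all(sites$cropland >= 0.03 & sites$cropland <= 0.98))
  # both crops span the gradient (stratified draws)
  expect_lt(min(sites$cropland[sites$crop == "apple"]), 0.1)
  expect_gt(max(sites$cropland[sites$crop == "apple"]), 0.9)
  cfg <- sim_config(cropland_range = c(0.5, 0.5))
  set.seed(1)
  expect_true(all(simulate_landscape(cfg)$cropland == 0.5))
})

test_that("residue generation respects detection probabilities and panel size", {
  cfg <- sim_config(detect_prob = c(apple = 0, oilseed_rape = 0))
  set.seed(2)
  sites <- simulate_landscape(cfg)
  res <- simulate_residues(sites, cfg)
  rp <- suppressWarnings(risk_profiles(res, reference_toxicity()))
  expect_true(all(rp$twc_mix == 0))
  expect_true(all(is.na(rp$mcr)))

  # single-compound panel forces MCR = 1 wherever anything is detected
  tox1 <- tiny_toxdb(compounds = "only", ld50 = 0.1, loq = 0.01)
  set.seed(3)
  res1 <- simulate_residues(sites, sim_config(), tox1,
                            conc_median = c(only = 50))
  rp1 <- risk_profiles(res1, tox1)
  expect_true(all(rp1$mcr[rp1$twc_mix > 0] == 1))
})

test_that("generated studies match the configured moments and mixture structure", {
  study <- simulate_study(seed = 8)
  g <- study$colonies$g_initial
  n <- length(g)
  # 3 Monte-Carlo SEs around the configured initial-weight moments
  expect_lt(abs(mean(g) - 648), 3 * 70.9 / sqrt(n))
  expect_lt(abs(sd(g) - 70.9), 3 * 70.9 / sqrt(2 * n))
  expect_true(abs(median(study$risk$n_compounds) - 8) <= 2)
  x <- study$risk$twc_mix
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 1)
  expect_gt(mean(study$risk$mcr < 1.5, na.rm = TRUE), 0.5)
  # weighing split: the max lands at the last weighing most often
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  frac3 <- mean(tab$gmax_weighing == 3)
  expect_gt(frac3, 0.45)
  expect_gt(mean(tab$gmax_weighing == 2), mean(tab$gmax_weighing == 1))
})

test_that("silencing every effect and variance gives identically zero weight gain", {
  cfg <- sim_config(
    lnrr = list(intercept = 0, b_g_initial = 0, b_risk = 0, b_risk_crop = 0,
                b_crop = 0, b_cropland = 0, b_risk_cropland = 0,
                b_crop_cropland = 0, b_risk_crop_cropland = 0,
                sd_country = 0, sd_site = 0, sd_resid = 0),
    n_lost = 0L)
  study <- simulate_study(cfg, seed = 10)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  # g_max = g_initial exactly, up to the 0.1 g recording precision
  expect_equal(tab$lnrr, rep(0, nrow(tab)), tolerance = 2e-4)
})

test_that("huge NB dispersion gives Poisson-like production counts", {
  cfg <- sim_config(
    production = list(intercept = log(50), b_g_initial = 0,
                      reduction_q90_vs_q25 = 0, b_crop = 0, b_cropland = 0,
                      b_risk_cropland = 0, theta = 1e8,
                      sd_country = 0, sd_site = 0),
    # keep queens rare so the caste split reconstructs production exactly
    queens = list(intercept = log(2), b_g_initial = 0,
                  reduction_q90_vs_q25 = 0, b_crop = 0, b_cropland = 0,
                  b_risk_cropland = 0, theta = 10, zi_prob = 0,
                  sd_country = 0, sd_site = 0),
    n_lost = 0L)
  study <- simulate_study(cfg, seed = 11)
  y <- study$colonies$intact_workermale + study$colonies$eclosed_workermale +
    study$colonies$intact_queen + study$colonies$eclosed_queen
  expect_equal(var(y) / mean(y), 1, tolerance = 0.35)
})

test_that("count effect sizes are derived from the configured reduction targets", {
  study <- simulate_study(seed = 13)
  truth <- study$truth
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  q <- quantile(tab$risk_c, c(0.25, 0.90), names = FALSE)
  # generator promise: exp(slope * (q90 - q25)) = 1 - reduction on the
  # site-level risk distribution it derived the slope from
  sites_rc <- prepare_risk_covariate(study$risk$twc_mix)
  qs <- quantile(sites_rc$values, c(0.25, 0.90), names = FALSE)
  expect_equal(exp(truth$production$b_risk * (qs[2] - qs[1])), 1 - 0.52,
               tolerance = 1e-10)
  expect_equal(exp(truth$queens$b_risk * (qs[2] - qs[1])), 1 - 0.47,
               tolerance = 1e-10)
  # colony-level quantiles sit close to the site-level ones
  expect_equal(q, qs, tolerance = 0.2)
})
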