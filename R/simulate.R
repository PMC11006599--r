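#' Synthetic sentinel-colony studies
#'
#' Generates complete synthetic studies — site network, pollen residue
#' samples, colony records — with the statistical structure the analysis
#' pipeline assumes: a multi-country site network spanning a cropland
#' gradient for two focal crops, mechanistically generated mixture risk
#' (compounds -> lognormal concentrations -> toxicity-weighted sums, so the
#' risk metrics sit inside the tested loop), and colony endpoints drawn from
#' the very model families the pipeline fits (Gaussian lnRR, NB2 counts,
#' zero-inflated queen counts, site-nested-in-country random intercepts).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 8
#' countries, 50 apple and 56 oilseed-rape sites (106 total, 318 colonies
#' at 3 per site), cropland spanning 3-98%, initial colony weight
#' 648 +/- 70.9 g, a risk slope for weight gain of -0.13 at apple and 0.02
#' at oilseed rape on the transformed centred scale, the colony maximum
#' weight landing at the third/second/first weighing with probability
#' 0.62/0.26/0.12, five colonies lost in the field, and count effect sizes
#' calibrated so the 90th- vs 25th-percentile risk contrast gives about a
#' 52% reduction in total production and 47% in queen production.
#'
#' @param ... Overrides for any default listed below.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_countries = 8L,
    sites_apple = 50L,
    sites_oilseed_rape = 56L,
    colonies_per_site = 3L,
    cropland_range = c(0.03, 0.98),
    g_initial_mean = 648,
    g_initial_sd = 70.9,
    # exposure: per-compound detection probability by crop (apple sites see
    # more compounds), lognormal concentrations around the reference survey
    # medians
    detect_prob = c(apple = 0.85, oilseed_rape = 0.75),
    conc_sdlog = 1.2,
    offset = 0.1,
    # weight gain (lnRR): Gaussian, site-level risk covariate
    lnrr = list(
      intercept = 0.35,
      b_g_initial = -8e-4,
      b_risk = -0.13,          # slope at apple
      b_risk_crop = 0.15,      # => slope at oilseed rape = 0.02
      b_crop = 0.08,
      b_cropland = -0.05,
      b_risk_cropland = -0.29,
      b_crop_cropland = 0,
      b_risk_crop_cropland = 0,
      sd_country = 0.10,
      sd_site = 0.12,
      sd_resid = 0.25),
    # total production: NB2, log link
    production = list(
      intercept = log(700),
      b_g_initial = 0,
      reduction_q90_vs_q25 = 0.52,  # defines the risk slope each draw
      b_crop = 0.15,
      b_cropland = -0.10,
      b_risk_cropland = -0.05,
      theta = 2,
      sd_country = 0.30,
      sd_site = 0.30),
    # queen production: zero-inflated NB2
    queens = list(
      intercept = log(45),
      b_g_initial = 0,
      reduction_q90_vs_q25 = 0.47,
      b_crop = 0,
      b_cropland = 0,
      b_risk_cropland = 0,
      theta = 1.5,
      zi_prob = 0.3,
      sd_country = 0.30,
      sd_site = 0.30),
    gmax_weighing_probs = c(0.12, 0.26, 0.62),
    n_lost = 5L,
    missing_pollen_site_frac = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        stop("unknown sim_config field(s) in '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  stopifnot(defaults$sites_apple >= 1, defaults$sites_oilseed_rape >= 1,
            defaults$colonies_per_site >= 1,
            all(defaults$detect_prob >= 0 & defaults$detect_prob <= 1),
            defaults$queens$zi_prob >= 0, defaults$queens$zi_prob <= 1)
  structure(defaults, class = "sim_config")
}

#' Null configuration (no risk effects)
#'
#' All risk coefficients set to zero (count reductions 0), for Type-I-error
#' calibration and null power checks.
#'
#' @param ... Passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_null <- function(...) {
  cfg <- sim_config(...)
  cfg$lnrr$b_risk <- 0
  cfg$lnrr$b_risk_crop <- 0
  cfg$lnrr$b_risk_cropland <- 0
  cfg$lnrr$b_risk_crop_cropland <- 0
  cfg$production$reduction_q90_vs_q25 <- 0
  cfg$production$b_risk_cropland <- 0
  cfg$queens$reduction_q90_vs_q25 <- 0
  cfg$queens$b_risk_cropland <- 0
  cfg
}

#' Simulate the site network
#'
#' Sites are assigned to countries round-robin; cropland is drawn uniform
#' over the configured range, stratified within each crop (one draw per
#' equal-width bin) so both crops span the whole gradient.
#'
#' @param config A `sim_config`.
#' @return Data frame: `site_id`, `country`, `crop`, `cropland`.
#' @export
simulate_landscape <- function(config = sim_config()) {
  n_a <- config$sites_apple
  n_o <- config$sites_oilseed_rape
  n <- n_a + n_o
  crop <- c(rep("apple", n_a), rep("oilseed_rape", n_o))
  lo <- config$cropland_range[1]; hi <- config$cropland_range[2]
  strat_unif <- function(k) {
    if (hi == lo) return(rep(lo, k))
    br <- seq(lo, hi, length.out = k + 1)
    sample(stats::runif(k, br[-(k + 1)], br[-1]))
  }
  cropland <- numeric(n)
  cropland[crop == "apple"] <- strat_unif(n_a)
  cropland[crop == "oilseed_rape"] <- strat_unif(n_o)
  data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    country = sprintf("C%d", (seq_len(n) - 1L) %% config$n_countries + 1L),
    crop = crop,
    cropland = cropland,
    stringsAsFactors = FALSE)
}

#' Simulate pollen residue samples
#'
#' Each panel compound is detected at a site with a crop-specific
#' probability; detected concentrations are lognormal around the
#' compound's reference median, then LOQ-censored. The resulting mixture
#' risk is strongly right-skewed and MCR concentrates near 1 (one compound
#' usually dominates), mirroring field surveys.
#'
#' @param sites Site table from [simulate_landscape()].
#' @param config A `sim_config`.
#' @param toxdb A `toxicity_db` (default the packaged reference fixture).
#' @param conc_median Named per-compound median concentrations (ug per kg)
#'   used as lognormal medians; defaults to the packaged survey summary.
#' @return A `residue_samples` data frame (censored).
#' @export
simulate_residues <- function(sites, config = sim_config(),
                              toxdb = reference_toxicity(),
                              conc_median = NULL) {
  if (is.null(conc_median)) {
    ref <- reference_residue_summary()
    conc_median <- stats::setNames(ref$conc_median, ref$compound_id)
  }
  panel <- panel_from_toxicity(toxdb)
  mlog <- log(conc_median[panel$compound_id])
  if (anyNA(mlog)) stop("missing median concentration for a panel compound",
                        call. = FALSE)
  n <- nrow(sites); k <- nrow(panel)
  p <- config$detect_prob[sites$crop]
  det <- matrix(stats::rbinom(n * k, 1L, rep(p, k)), nrow = n)
  conc <- matrix(stats::rlnorm(n * k, rep(mlog, each = n), config$conc_sdlog),
                 nrow = n)
  conc <- conc * det
  colnames(conc) <- panel$compound_id
  residue_samples(sites$site_id, conc, panel)
}

.count_risk_slope <- function(reduction, risk_c) {
  if (reduction <= 0) return(0)
  q <- stats::quantile(risk_c, c(0.25, 0.90), names = FALSE, type = 7)
  if (q[2] <= q[1]) return(0)
  log(1 - reduction) / (q[2] - q[1])
}

#' Simulate colony records
#'
#' Country and site random intercepts are drawn normal per response; the
#' fixed linear predictor uses the transformed centred risk covariate, crop
#' (apple reference), centred cropland and centred initial weight, with the
#' configured interactions. lnRR is Gaussian around its predictor, g_max is
#' back-solved from the simulated g_initial, and the three field weighings
#' are constructed so the maximum lands at the third/second/first weighing
#' with the configured probabilities. Production is NB2, queens
#' zero-inflated NB2. The count risk slopes are derived from the configured
#' 90th- vs 25th-percentile reduction targets on the realized risk
#' distribution. A configurable number of colonies is flagged lost and a
#' configurable fraction of sites flagged with insufficient stored pollen.
#'
#' @param sites Site table.
#' @param risk A `risk_profile` for those sites.
#' @param config A `sim_config`.
#' @return List: `colonies` (data frame of colony records) and `truth`
#'   (generating parameters actually used, including the derived count risk
#'   slopes and the risk centring mean).
#' @export
simulate_colonies <- function(sites, risk, config = sim_config()) {
  stopifnot(all(sites$site_id %in% risk$site_id))
  n_sites <- nrow(sites)
  m <- config$colonies_per_site
  n <- n_sites * m

  rc <- prepare_risk_covariate(
    risk$twc_mix[match(sites$site_id, risk$site_id)], offset = config$offset)
  risk_c <- rc$values
  cropland_c <- sites$cropland - mean(sites$cropland)
  is_osr <- as.numeric(sites$crop == "oilseed_rape")
  countries <- sort(unique(sites$country))

  site_idx <- rep(seq_len(n_sites), each = m)
  g_initial <- stats::rnorm(n, config$g_initial_mean, config$g_initial_sd)
  g_initial <- pmax(g_initial, 50)
  g_c <- g_initial - mean(g_initial)

  eta_fixed <- function(p, b_risk, site_level = FALSE) {
    e <- p$intercept +
      b_risk * risk_c +
      (p$b_risk_crop %||% 0) * risk_c * is_osr +
      p$b_crop * is_osr +
      p$b_cropland * cropland_c +
      p$b_risk_cropland * risk_c * cropland_c +
      (p$b_crop_cropland %||% 0) * is_osr * cropland_c +
      (p$b_risk_crop_cropland %||% 0) * risk_c * is_osr * cropland_c
    if (site_level) e else e[site_idx]
  }
  draw_re <- function(p) {
    u_country <- stats::setNames(
      stats::rnorm(length(countries), 0, p$sd_country), countries)
    u_site <- stats::rnorm(n_sites, 0, p$sd_site)
    (u_country[sites$country] + u_site)[site_idx]
  }

  # weight gain
  pl <- config$lnrr
  lnrr <- eta_fixed(pl, pl$b_risk) + pl$b_g_initial * g_c + draw_re(pl) +
    stats::rnorm(n, 0, pl$sd_resid)
  g_max <- g_initial * exp(lnrr)

  # field weighing triplet: max at position 3/2/1 with configured probs
  pos <- sample(1:3, n, replace = TRUE, prob = config$gmax_weighing_probs)
  w <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    others <- g_max[i] * stats::runif(2, 0.70, 0.98)
    w[i, ] <- c(others, g_max[i])[order(c(setdiff(1:3, pos[i]), pos[i]))]
  }

  # total production (NB2)
  pp <- config$production
  b_risk_prod <- .count_risk_slope(pp$reduction_q90_vs_q25, risk_c)
  mu_prod <- exp(eta_fixed(pp, b_risk_prod) + pp$b_g_initial * g_c + draw_re(pp))
  prod_total <- stats::rnbinom(n, mu = mu_prod, size = pp$theta)

  # queen production (ZINB)
  pq <- config$queens
  b_risk_queen <- .count_risk_slope(pq$reduction_q90_vs_q25, risk_c)
  mu_q <- exp(eta_fixed(pq, b_risk_queen) + pq$b_g_initial * g_c + draw_re(pq))
  queens <- stats::rnbinom(n, mu = mu_q, size = pq$theta)
  queens[stats::runif(n) < pq$zi_prob] <- 0L

  # split counts across castes: queens intact/eclosed, remainder worker/male
  q_intact <- stats::rbinom(n, queens, 0.6)
  wm <- pmax(prod_total - queens, 0L)
  wm_intact <- stats::rbinom(n, wm, 0.5)

  colonies <- data.frame(
    colony_id = sprintf("%s_col%d", sites$site_id[site_idx],
                        rep(seq_len(m), times = n_sites)),
    site_id = sites$site_id[site_idx],
    g_initial = round(g_initial, 1),
    weight_1 = round(w[, 1], 1),
    weight_2 = round(w[, 2], 1),
    weight_3 = round(w[, 3], 1),
    intact_workermale = wm_intact,
    eclosed_workermale = wm - wm_intact,
    intact_queen = q_intact,
    eclosed_queen = queens - q_intact,
    status = "ok",
    status_reason = "",
    stringsAsFactors = FALSE)

  if (config$missing_pollen_site_frac > 0) {
    bad_sites <- sample(sites$site_id,
                        round(config$missing_pollen_site_frac * n_sites))
    hit <- colonies$site_id %in% bad_sites
    colonies$status[hit] <- "insufficient_pollen"
    colonies$status_reason[hit] <- "not enough stored pollen for residue analysis"
  }
  if (config$n_lost > 0) {
    ok_idx <- which(colonies$status == "ok")
    lost <- sample(ok_idx, min(config$n_lost, length(ok_idx)))
    colonies$status[lost] <- "lost"
    colonies$status_reason[lost] <- "colony lost in the field"
  }

  truth <- list(
    lnrr = pl,
    production = c(pp, b_risk = b_risk_prod),
    queens = c(pq, b_risk = b_risk_queen),
    risk_centring_mean = rc$centring_mean,
    risk_sd = rc$sd,
    cropland_mean = mean(sites$cropland))
  list(colonies = colonies, truth = truth)
}

#' Simulate a complete study
#'
#' Runs landscape -> residues -> risk -> colonies under one seed, with a
#' deterministic substream per stage, so regenerating with the same config
#' and seed is bit-identical.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List of class `synthetic_study`: `sites`, `residues`, `toxicity`,
#'   `risk`, `colonies`, `truth`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  toxdb <- reference_toxicity()
  set.seed(seed)
  stage_seeds <- sample.int(2^31 - 1, 3)
  set.seed(stage_seeds[1])
  sites <- simulate_landscape(config)
  set.seed(stage_seeds[2])
  residues <- simulate_residues(sites, config, toxdb)
  risk <- risk_profiles(residues, toxdb)
  set.seed(stage_seeds[3])
  col <- simulate_colonies(sites, risk, config)
  structure(
    list(sites = sites, residues = residues, toxicity = toxdb, risk = risk,
         colonies = col$colonies, truth = col$truth, seed = seed),
    class = "synthetic_study")
}

#' Write a synthetic study to CSV inputs plus truth.json
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "residues.csv", "toxicity.csv",
                            "colonies.csv", "truth.json"))
  utils::write.csv(study$sites, paths[1], row.names = FALSE)
  utils::write.csv(study$residues, paths[2], row.names = FALSE)
  tox_long <- utils::read.csv(
    system.file("extdata", "ld50_top10.csv", package = "pollenrisk"))
  utils::write.csv(tox_long, paths[3], row.names = FALSE)
  utils::write.csv(study$colonies, paths[4], row.names = FALSE)
  jsonlite::write_json(study$truth, paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Power curve for the risk x cropland interaction
#'
#' Simulates studies of increasing size, fits the weight-gain LMM and
#' records how often the risk x cropland Wald test rejects at `alpha`.
#' Crop shares and everything else follow `config`; `site_counts` scales
#' the number of sites (colony-site combinations = sites x colonies per
#' site).
#'
#' @param config A `sim_config`.
#' @param site_counts Integer vector of total site numbers to test.
#' @param n_reps Replicates per size (>= 50 recommended for stable
#'   estimates).
#' @param seed Integer seed.
#' @param alpha Test size (default 0.05).
#' @return Data frame `n_sites`, `n_combinations`, `power`, with attribute
#'   `n80`: the smallest number of colony-site combinations reaching 0.8
#'   power (`NA` if none did).
#' @export
power_curve <- function(config = sim_config(), site_counts = c(25, 50, 75, 106),
                        n_reps = 100, seed = 1L, alpha = 0.05) {
  share_apple <- config$sites_apple /
    (config$sites_apple + config$sites_oilseed_rape)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2^31 - 1, length(site_counts) * n_reps),
                      nrow = length(site_counts))
  power <- numeric(length(site_counts))
  for (i in seq_along(site_counts)) {
    ns <- site_counts[i]
    cfg <- config
    cfg$sites_apple <- max(1L, round(share_apple * ns))
    cfg$sites_oilseed_rape <- max(1L, ns - cfg$sites_apple)
    # keep losses proportionate to design size
    cfg$n_lost <- round(config$n_lost * ns /
                          (config$sites_apple + config$sites_oilseed_rape))
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      study <- simulate_study(cfg, seed = rep_seeds[i, r])
      tab <- build_analysis_table(study$colonies, study$risk, study$sites,
                                  offset = cfg$offset)
      fit <- suppressMessages(suppressWarnings(fit_lmm(tab)))
      an <- wald_anova(fit)
      rej[r] <- an$p[an$term == "risk_c:cropland_c"] < alpha
    }
    power[i] <- mean(rej)
  }
  out <- data.frame(n_sites = site_counts,
                    n_combinations = site_counts * config$colonies_per_site,
                    power = power)
  reach <- which(power >= 0.8)
  attr(out, "n80") <- if (length(reach)) out$n_combinations[min(reach)] else NA
  out
}
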