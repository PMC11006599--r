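test_that("maximum weight picks the peak, ties resolve to the latest weighing", {
  m <- max_weight(c(700, 900, 850))
  expect_equal(as.numeric(m), 900)
  expect_equal(attr(m, "index"), 2L)
  m <- max_weight(c(800, 800))
  expect_equal(as.numeric(m), 800)
  expect_equal(attr(m, "index"), 2L)
  expect_equal(as.numeric(max_weight(650)), 650)
  m <- max_weight(c(NA, 720, NA))
  expect_equal(attr(m, "index"), 2L)
  expect_error(max_weight(c(NA, NA)), "no field weighings")
  expect_error(max_weight(c(-5, 700)), "positive")
})

test_that("weight-gain lnRR is the log ratio and is unit invariant", {
  expect_equal(weight_gain_lnrr(648, 648), 0)
  expect_equal(weight_gain_lnrr(500, 1000), log(2))
  expect_equal(weight_gain_lnrr(800, 400), -log(2))
  g <- c(648, 712, 533)
  m <- c(901, 655, 1204)
  expect_equal(weight_gain_lnrr(g, m), weight_gain_lnrr(g / 1000, m / 1000))
  expect_error(weight_gain_lnrr(0, 100), "positive")
})

test_that("production endpoints sum cocoons; queens count toward the total", {
  expect_equal(total_production(200, 150, 10, 5), 365L)
  expect_equal(total_production(0, 0, 0, 0), 0L)
  expect_equal(total_production(0, 0, 3, 0), 3L)
  expect_equal(queen_production(12, 9), 21L)
  expect_equal(queen_production(0, 45), 45L)
  expect_error(total_production(-1, 0, 0, 0), "nonnegative")
  set.seed(17)
  cnt <- matrix(rpois(40, 20), ncol = 4)
  expect_true(all(
    total_production(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4]) >=
      queen_production(cnt[, 3], cnt[, 4])))
})

test_that("the analysis table joins risk, derives endpoints and logs exclusions", {
  st <- tiny_study()
  tab <- build_analysis_table(st$colonies, st$risk, st$sites)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$g_max[1:3], c(900, 800, 650))
  expect_equal(tab$gmax_weighing[1:3], c(2L, 2L, 1L))
  expect_equal(tab$lnrr[1], log(900 / 600))
  expect_equal(tab$total_production[1:3], c(365L, 250L, 3L))
  expect_equal(tab$queen_production[1:3], c(15L, 0L, 3L))
  expect_equal(unique(tab$twc_mix), c(100, 101, 0, 27.5))
  expect_equal(mean(tab$risk_c), 0, tolerance = 1e-12)
  expect_equal(mean(tab$cropland_c), 0, tolerance = 1e-12)
  expect_equal(levels(tab$crop), c("apple", "oilseed_rape"))
  expect_equal(nrow(attr(tab, "exclusions")), 0)
})

test_that("excluded colonies disappear with a reason; counts match a direct tally", {
  st <- tiny_study()
  col <- st$colonies
  col$status[c(1, 5)] <- "lost"
  col$status[7:9] <- "insufficient_pollen"
  tab <- build_analysis_table(col, st$risk, st$sites)
  expect_equal(nrow(tab), sum(col$status == "ok"))
  expect_equal(sort(attr(tab, "exclusions")$colony_id),
               sort(col$colony_id[col$status != "ok"]))
  # raw values of included colonies unchanged; only centring shifts
  full <- build_analysis_table(st$colonies, st$risk, st$sites)
  keep <- full$colony_id %in% tab$colony_id
  expect_equal(tab$twc_mix, full$twc_mix[keep])
  expect_equal(tab$lnrr, full$lnrr[keep])
  shift <- attr(full, "risk_covariate")$centring_mean -
    attr(tab, "risk_covariate")$centring_mean
  expect_equal(tab$risk_c, full$risk_c[keep] + shift)
})

test_that("exclusion bookkeeping scales to a deployed-design simulation", {
  cfg <- sim_config(sites_apple = 64L, sites_oilseed_rape = 64L,
                    missing_pollen_site_frac = 21 / 128, n_lost = 5L)
  study <- simulate_study(cfg, seed = 99)
  expect_equal(nrow(study$colonies), 384)
  tab <- build_analysis_table(study$colonies, study$risk, study$sites)
  # counting oracle: included = all minus flagged
  expect_equal(nrow(tab), sum(study$colonies$status == "ok"))
  expect_equal(nrow(tab) + nrow(attr(tab, "exclusions")), 384)
  expect_equal(sum(attr(tab, "exclusions")$reason ==
                     "colony lost in the field"), 5)
})

test_that("a colony at a site without a risk profile is a hard error", {
  st <- tiny_study()
  risk <- st$risk[st$risk$site_id != "S3", ]
  expect_error(build_analysis_table(st$colonies, risk, st$sites), "S3")
  sites <- st$sites[st$sites$site_id != "S2", ]
  expect_error(build_analysis_table(st$colonies, st$risk, sites), "S2")
})
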