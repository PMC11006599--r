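# Small deterministic fixtures built in code.

# Two-compound toxicity table written to a temp CSV and loaded through the
# public reader, so fixture records carry the same invariants as real ones.
tiny_toxdb <- function(compounds = c("alpha", "beta"),
                       ld50 = c(0.05, 10), loq = c(1, 1)) {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(
    compound_id = compounds,
    pesticide_type = "insecticide",
    chemical_group = "Test",
    route = "oral",
    time_h = 24,
    ld50_ug_per_bee = ld50,
    qualifier = "exact",
    loq_ug_per_kg = loq)
  utils::write.csv(df, path, row.names = FALSE)
  load_toxicity_table(path)
}

# Four-site, three-colony deterministic study for endpoint arithmetic.
tiny_study <- function() {
  sites <- data.frame(
    site_id = c("S1", "S2", "S3", "S4"),
    country = c("A", "A", "B", "B"),
    crop = c("apple", "oilseed_rape", "apple", "oilseed_rape"),
    cropland = c(0.1, 0.4, 0.6, 0.9),
    stringsAsFactors = FALSE)
  toxdb <- tiny_toxdb()
  conc <- matrix(0, nrow = 4, ncol = 2,
                 dimnames = list(NULL, c("alpha", "beta")))
  conc[1, ] <- c(5, 0)      # single compound -> MCR 1
  conc[2, ] <- c(5, 10)     # TWC 100 + 1
  conc[3, ] <- c(0, 0)      # zero risk
  conc[4, ] <- c(1.25, 25)  # TWC 25 + 2.5
  residues <- residue_samples(sites$site_id, conc, panel_from_toxicity(toxdb))
  colonies <- data.frame(
    colony_id = sprintf("c%02d", 1:12),
    site_id = rep(sites$site_id, each = 3),
    g_initial = rep(c(600, 650, 700), 4),
    weight_1 = rep(c(700, 800, 650), 4),
    weight_2 = rep(c(900, 800, 640), 4),
    weight_3 = rep(c(850, 700, 630), 4),
    intact_workermale = rep(c(200, 150, 0), 4),
    eclosed_workermale = rep(c(150, 100, 0), 4),
    intact_queen = rep(c(10, 0, 3), 4),
    eclosed_queen = rep(c(5, 0, 0), 4),
    status = "ok",
    status_reason = "",
    stringsAsFactors = FALSE)
  list(sites = sites, toxdb = toxdb, residues = residues, colonies = colonies,
       risk = risk_profiles(residues, toxdb))
}

# Grouped covariate data for reduced model fits (single random intercept).
grouped_data <- function(n_groups, n_per, seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = n_per))
  data.frame(g = g, x = stats::rnorm(n_groups * n_per))
}
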