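#' End-to-end pipeline
#'
#' One call runs residues -> risk -> endpoints -> models and writes the
#' report bundle: per-sample risk, the ranked compound-risk table, one
#' Wald-chi-square table per response with R2 footer rows, diagnostics and
#' a run manifest. All randomness flows from the single configured seed.
#'
#' @name pipeline_cli
NULL

#' Pipeline run configuration
#'
#' @param simulate Generate the study synthetically (`TRUE`, default) or
#'   read it from `inputs`.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param inputs Named list of CSV paths (`sites`, `residues`, `toxicity`,
#'   `colonies`) used when `simulate = FALSE`.
#' @param seed Integer seed recorded in all outputs.
#' @param out_dir Output directory.
#' @param denominator Detection-frequency denominator for compound risk
#'   (default 100, the per-cent convention).
#' @param offset Log offset for the risk covariate (default 0.1).
#' @param responses Character vector of models to fit, any of `"lnrr"`,
#'   `"total_production"`, `"g_max"`, `"queen_production"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            inputs = NULL, seed = 1L, out_dir = "pollenrisk_run",
                            denominator = 100, offset = 0.1,
                            responses = c("lnrr", "total_production", "g_max",
                                          "queen_production")) {
  known <- c("lnrr", "total_production", "g_max", "queen_production")
  bad <- setdiff(responses, known)
  if (length(bad)) {
    stop("unknown response(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!simulate && (is.null(inputs) ||
                    !all(c("sites", "residues", "toxicity", "colonies") %in%
                         names(inputs)))) {
    stop("inputs must name sites, residues, toxicity and colonies files",
         call. = FALSE)
  }
  structure(list(simulate = simulate, sim = sim, inputs = inputs,
                 seed = as.integer(seed), out_dir = out_dir,
                 denominator = denominator, offset = offset,
                 responses = responses),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Ranked compound-risk report
#'
#' Joins per-compound detection summaries to the toxicity database and
#' ranks compounds by descending individual compound risk (ties broken by
#' compound id for a stable ordering).
#'
#' @param summaries Data frame from [compound_summaries()] (or with the
#'   same columns, e.g. [reference_residue_summary()]).
#' @param toxdb A `toxicity_db`.
#' @param denominator Detection-frequency denominator (default 100).
#' @param top_k Keep only the k riskiest compounds (default all).
#' @return Data frame: compound identity/class columns, effective `ld50`,
#'   `limit_test`, `loq`, concentration statistics, `n_detect`,
#'   `freq_pct`, `compound_risk`, sorted by risk.
#' @export
report_table2 <- function(summaries, toxdb, denominator = 100, top_k = Inf) {
  i <- match(summaries$compound_id, toxdb$compound_id)
  if (anyNA(i)) {
    stop("no toxicity data for: ",
         paste(summaries$compound_id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  risk <- vapply(seq_len(nrow(summaries)), function(k) {
    if (summaries$n_detect[k] == 0) return(0)
    compound_risk(summaries$conc_mean[k], toxdb$ld50[i[k]],
                  summaries$n_detect[k], denominator)
  }, 0)
  out <- data.frame(
    compound_id = summaries$compound_id,
    pesticide_type = toxdb$pesticide_type[i],
    chemical_group = toxdb$chemical_group[i],
    ld50 = toxdb$ld50[i],
    limit_test = toxdb$limit_test[i],
    loq = toxdb$loq[i],
    conc_mean = summaries$conc_mean,
    conc_median = summaries$conc_median,
    conc_p90 = summaries$conc_p90,
    n_detect = summaries$n_detect,
    freq_pct = round(100 * summaries$n_detect / summaries$n_sites),
    compound_risk = risk,
    stringsAsFactors = FALSE)
  out <- out[order(-out$compound_risk, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Wald-table model report
#'
#' Per-term chi-square and P (P rounded to 2 significant figures for
#' display) with marginal and conditional R2 footer rows, mirroring the
#' layout of a main-results table.
#'
#' @param fit A converged `colony_fit`.
#' @return Data frame with columns `term`, `chisq`, `p`; the last two rows
#'   carry the R2 values in the `chisq` column.
#' @export
model_report <- function(fit) {
  an <- wald_anova(fit)
  r2 <- r2_nakagawa(fit)
  rbind(
    data.frame(term = an$term, chisq = round(an$chisq, 2),
               p = signif(an$p, 2), stringsAsFactors = FALSE),
    data.frame(term = c("R2_marginal", "R2_conditional"),
               chisq = round(c(r2$marginal, r2$conditional), 2),
               p = NA_real_, stringsAsFactors = FALSE))
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the analysis table, fits, reports and the
#'   output paths. Writes, under `config$out_dir`: `risk.csv`,
#'   `compound_risk.csv`, `anova_<response>.csv`, `diagnostics.json` and
#'   `manifest.json`. Any stage error aborts with the stage name;
#'   `INCOMPLETE` marker files are left if a later stage fails.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  file.create(marker)

  if (config$simulate) {
    study <- .stage("simulate", simulate_study(config$sim, seed = config$seed))
    sites <- study$sites; residues <- study$residues
    toxdb <- study$toxicity; colonies <- study$colonies
  } else {
    toxdb <- .stage("toxicity", load_toxicity_table(config$inputs$toxicity))
    sites <- .stage("sites", utils::read.csv(config$inputs$sites,
                                             stringsAsFactors = FALSE))
    residues <- .stage("residues", read_residue_table(
      config$inputs$residues, panel_from_toxicity(toxdb)))
    colonies <- .stage("colonies", utils::read.csv(config$inputs$colonies,
                                                   stringsAsFactors = FALSE))
  }

  risk <- .stage("risk", risk_profiles(residues, toxdb))
  summaries <- .stage("summaries",
                      compound_summaries(residues, panel_from_toxicity(toxdb)))
  tab <- .stage("endpoints",
                build_analysis_table(colonies, risk, sites,
                                     offset = config$offset))

  fitters <- list(
    lnrr = function(d) fit_lmm(d, "lnrr"),
    total_production = function(d) fit_nb_glmm(d, "total_production"),
    g_max = function(d) fit_lmm(d, "g_max", log_response = TRUE),
    queen_production = function(d) fit_zinb_glmm(d, "queen_production"))
  fits <- list()
  reports <- list()
  for (resp in config$responses) {
    fits[[resp]] <- .stage(paste0("fit_", resp),
                           suppressMessages(suppressWarnings(fitters[[resp]](tab))))
    reports[[resp]] <- .stage(paste0("report_", resp),
                              model_report(fits[[resp]]))
  }

  risk_path <- file.path(config$out_dir, "risk.csv")
  utils::write.csv(risk, risk_path, row.names = FALSE)
  cmp_path <- file.path(config$out_dir, "compound_risk.csv")
  utils::write.csv(report_table2(summaries, toxdb, config$denominator),
                   cmp_path, row.names = FALSE)
  for (resp in names(reports)) {
    utils::write.csv(reports[[resp]],
                     file.path(config$out_dir, paste0("anova_", resp, ".csv")),
                     row.names = FALSE)
  }
  diag <- lapply(fits, function(f) {
    d <- diagnostics(f)
    list(dispersion_ratio = d$dispersion_ratio, vif = as.list(d$vif))
  })
  jsonlite::write_json(diag, file.path(config$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "pollenrisk",
    version = as.character(utils::packageVersion("pollenrisk")),
    seed = config$seed,
    simulate = config$simulate,
    denominator = config$denominator,
    offset = config$offset,
    responses = config$responses,
    n_colonies = nrow(tab),
    n_sites = length(unique(tab$site_id)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  file.remove(marker)
  invisible(list(analysis_table = tab, fits = fits, reports = reports,
                 risk = risk, out_dir = config$out_dir))
}
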