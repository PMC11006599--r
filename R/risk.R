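#' Toxicity-weighted mixture risk metrics
#'
#' The risk carried by compound i in a pollen sample is its
#' toxicity-weighted concentration, TWC_i = c_i / LD50_i, the residue
#' concentration (ug per kg) divided by the compound's effective acute LD50
#' (ug per bee). Under concentration addition the sample's mixture risk is
#' the sum TWC_mix = sum_i TWC_i, and the maximum cumulative ratio
#' MCR = TWC_mix / max_i(TWC_i) measures how much riskier the whole mixture
#' is than its single riskiest component: MCR = 1 when one compound carries
#' all the risk, and at most the number of detected compounds.
#'
#' @name risk_metrics
NULL

#' Toxicity-weighted concentration of one compound
#'
#' @param concentration Concentration in pollen, ug per kg (>= 0).
#' @param ld50 Effective acute LD50, ug per bee (> 0).
#' @return `concentration / ld50`, units (ug per kg) / (ug per bee); treated
#'   throughout as a relative risk index, never rescaled.
#' @examples
#' twc(5, 0.05) # 100
#' @export
twc <- function(concentration, ld50) {
  if (any(!is.finite(ld50) | ld50 <= 0)) {
    stop("ld50 must be strictly positive", call. = FALSE)
  }
  if (any(concentration < 0)) {
    stop("concentration must be nonnegative", call. = FALSE)
  }
  concentration / ld50
}

.sample_conc <- function(sample, toxdb) {
  # named concentration vector for one sample (list / named vector / one-row
  # residue_samples slice), checked against the toxicity db
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L)
    sample <- unlist(sample[, setdiff(names(sample), "site_id"), drop = FALSE])
  }
  conc <- unlist(sample)
  if (length(conc) && is.null(names(conc))) {
    stop("sample concentrations must be named by compound", call. = FALSE)
  }
  missing_tox <- names(conc)[conc > 0 & !(names(conc) %in% toxdb$compound_id)]
  if (length(missing_tox)) {
    stop("positive concentration without toxicity data for: ",
         paste(missing_tox, collapse = ", "), call. = FALSE)
  }
  conc
}

#' Additive mixture risk of a sample
#'
#' @param sample Named concentrations (ug per kg) for one sample: a named
#'   vector/list or a one-row slice of a `residue_samples` data frame.
#' @param toxdb A `toxicity_db`; every compound with a positive
#'   concentration must be present (missing toxicity is an error, never a
#'   silent drop).
#' @return TWC_mix, the sum of per-compound toxicity-weighted
#'   concentrations; 0 for an empty or all-censored sample.
#' @export
twc_mix <- function(sample, toxdb) {
  sum(twc_by_compound(sample, toxdb))
}

#' Per-compound toxicity-weighted concentrations of a sample
#'
#' @inheritParams twc_mix
#' @return Named vector of TWC_i over the compounds with positive
#'   concentration (empty vector when nothing was quantified).
#' @export
twc_by_compound <- function(sample, toxdb) {
  conc <- .sample_conc(sample, toxdb)
  conc <- conc[conc > 0]
  if (!length(conc)) return(stats::setNames(numeric(0), character(0)))
  ld50 <- toxdb$ld50[match(names(conc), toxdb$compound_id)]
  stats::setNames(twc(as.numeric(conc), ld50), names(conc))
}

#' Maximum cumulative ratio
#'
#' @param twcs Named (or plain) vector of per-compound toxicity-weighted
#'   concentrations for one sample.
#' @return `sum(twcs) / max(twcs)`, in `[1, n]` where n is the number of
#'   positive components; exactly 1 when a single compound carries all
#'   risk. `NA` (with a warning) when the total risk is zero — the MCR is
#'   undefined there, while the sample keeps TWC_mix = 0 for modelling.
#' @export
mcr <- function(twcs) {
  twcs <- twcs[twcs > 0]
  if (!length(twcs)) {
    warning("MCR undefined for a zero-risk sample", call. = FALSE)
    return(NA_real_)
  }
  sum(twcs) / max(twcs)
}

#' Risk profiles for a set of samples
#'
#' @param samples A `residue_samples` data frame (one row per site).
#' @param toxdb A `toxicity_db`.
#' @return Data frame of class `risk_profile`: `site_id`, `twc_mix`, `mcr`
#'   (`NA` for zero-risk samples), `n_compounds` (positive detections) and
#'   `max_compound_id` (the dominant compound, `NA` when none).
#' @export
risk_profiles <- function(samples, toxdb) {
  comp_cols <- setdiff(names(samples), "site_id")
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    conc <- unlist(samples[i, comp_cols, drop = FALSE])
    tw <- twc_by_compound(conc, toxdb)
    data.frame(
      site_id = samples$site_id[i],
      twc_mix = sum(tw),
      mcr = if (length(tw)) sum(tw) / max(tw) else NA_real_,
      n_compounds = length(tw),
      max_compound_id = if (length(tw)) names(tw)[which.max(tw)] else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_profile", "data.frame")
  out
}

#' Individual compound risk score
#'
#' Ranks single compounds by population-level risk: the mean concentration
#' over positive samples, divided by the compound's effective LD50, times
#' the site detection frequency `n_detect / denominator`.
#'
#' @param mean_conc_positives Mean concentration over positive samples, ug
#'   per kg.
#' @param ld50 Effective LD50, ug per bee.
#' @param n_detect Number of sites with a positive (quantified) sample.
#' @param denominator Frequency denominator; the default 100 reproduces the
#'   published per-cent convention (frequencies reported as whole per cent
#'   of sites), override with the true site count to use exact proportions.
#' @return The risk score; 0 (with a warning) when `n_detect` is 0.
#' @examples
#' compound_risk(31, 0.100, 11) # 34.1
#' @export
compound_risk <- function(mean_conc_positives, ld50, n_detect,
                          denominator = 100) {
  stopifnot(denominator > 0)
  if (n_detect == 0) {
    warning("compound never detected: risk score 0", call. = FALSE)
    return(0)
  }
  stopifnot(mean_conc_positives > 0, ld50 > 0)
  (mean_conc_positives / ld50) * (n_detect / denominator)
}

#' Model-ready risk covariate
#'
#' Mixture risk is strongly right-skewed, so the modelling covariate is
#' ln(x + 0.1), then centred; the offset keeps zero-risk samples defined
#' and the centring mean is stored so slopes can be evaluated at
#' interpretable (e.g. "+1 s.d.") settings and back-transformed.
#'
#' @param x Per-site TWC_mix values (>= 0).
#' @param offset Log offset, default 0.1.
#' @param center Either `TRUE` (centre at the sample mean), `FALSE`, or a
#'   numeric centring constant (used when re-centring an exclusion-filtered
#'   set on a stored mean).
#' @return List of class `risk_covariate`: `values` (transformed, centred),
#'   `offset`, `centring_mean`, `sd` (of the transformed values).
#' @export
prepare_risk_covariate <- function(x, offset = 0.1, center = TRUE) {
  if (any(x < 0)) stop("risk values must be nonnegative", call. = FALSE)
  lx <- log(x + offset)
  mu <- if (isTRUE(center)) mean(lx) else if (identical(center, FALSE)) 0 else as.numeric(center)
  structure(
    list(values = lx - mu, offset = offset, centring_mean = mu,
         sd = stats::sd(lx)),
    class = "risk_covariate")
}
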