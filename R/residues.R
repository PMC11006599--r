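#' Residue tables, LOQ censoring and detection summaries
#'
#' Residue concentrations in pooled pollen samples are left-censored at each
#' compound's limit of quantification (LOQ): any value strictly below the
#' LOQ — and any missing value — is treated as zero, so a zero downstream
#' means "not quantified". Values exactly at the LOQ are kept.
#'
#' @name residue_io
NULL

#' Build a residue screening panel
#'
#' The panel is the ordered list of compounds a sample was screened for,
#' with each compound's LOQ.
#'
#' @param compound_id Character vector of unique compound ids.
#' @param loq Positive numeric vector of LOQs (ug per kg), recycled if
#'   length 1.
#' @return Data frame of class `residue_panel` with columns `compound_id`,
#'   `loq`.
#' @export
residue_panel <- function(compound_id, loq) {
  if (anyDuplicated(compound_id)) {
    stop("panel compound ids must be unique", call. = FALSE)
  }
  loq <- rep_len(loq, length(compound_id))
  if (any(!is.finite(loq) | loq <= 0)) {
    stop("panel LOQ values must be strictly positive", call. = FALSE)
  }
  structure(
    data.frame(compound_id = as.character(compound_id), loq = loq,
               stringsAsFactors = FALSE),
    class = c("residue_panel", "data.frame"))
}

#' @describeIn residue_panel Panel derived from a `toxicity_db` (same
#'   compounds and LOQs).
#' @param toxdb A `toxicity_db` from [load_toxicity_table()].
#' @export
panel_from_toxicity <- function(toxdb) {
  residue_panel(toxdb$compound_id, toxdb$loq)
}

#' Censor a concentration below the limit of quantification
#'
#' @param raw Raw concentration(s), ug per kg; `NA` means not detected.
#' @param loq Positive LOQ(s), ug per kg.
#' @return Censored concentration: 0 when `raw` is missing or `< loq`,
#'   otherwise `raw` unchanged (a value exactly at the LOQ is kept).
#' @examples
#' censor_below_loq(4.9, 5) # 0
#' censor_below_loq(5.0, 5) # 5
#' @export
censor_below_loq <- function(raw, loq) {
  if (any(!is.finite(loq) | loq <= 0)) {
    stop("loq must be strictly positive", call. = FALSE)
  }
  if (any(raw < 0, na.rm = TRUE)) {
    stop("negative residue concentration", call. = FALSE)
  }
  out <- ifelse(is.na(raw) | raw < loq, 0, raw)
  out
}

#' Read a wide residue table and apply LOQ censoring
#'
#' @param path CSV, first column `site_id`, remaining columns compound ids
#'   from the panel, cells concentrations in ug per kg (blank = not
#'   detected).
#' @param panel A `residue_panel`.
#' @return Data frame of class `residue_samples`: column `site_id` plus one
#'   censored concentration column per panel compound (compounds never
#'   reported come back as all-zero columns). Sites with no positive value
#'   are retained.
#' @export
read_residue_table <- function(path, panel) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "site_id") {
    stop("residue table must have 'site_id' as its first column", call. = FALSE)
  }
  if (anyDuplicated(raw$site_id)) {
    stop("duplicate site_id in residue table: ",
         raw$site_id[which(duplicated(raw$site_id))[1]], call. = FALSE)
  }
  unknown <- setdiff(names(raw)[-1], panel$compound_id)
  if (length(unknown)) {
    stop("residue table has compounds not on the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (j in names(raw)[-1]) {
    if (!is.numeric(raw[[j]]) && !all(is.na(raw[[j]]))) {
      stop("non-numeric concentration in column '", j, "'", call. = FALSE)
    }
  }
  out <- data.frame(site_id = as.character(raw$site_id),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(panel))) {
    cid <- panel$compound_id[k]
    v <- if (cid %in% names(raw)) as.numeric(raw[[cid]]) else rep(NA_real_, nrow(raw))
    out[[cid]] <- censor_below_loq(v, panel$loq[k])
  }
  class(out) <- c("residue_samples", "data.frame")
  out
}

#' Assemble residue samples from a wide matrix in memory
#'
#' Same contract as [read_residue_table()] but starting from data already in
#' R (used by the synthetic generator and the pipeline).
#'
#' @param site_id Character vector of unique site ids.
#' @param conc Numeric matrix, rows = sites, columns named by panel
#'   compound; raw (uncensored) concentrations.
#' @param panel A `residue_panel`.
#' @return A `residue_samples` data frame.
#' @export
residue_samples <- function(site_id, conc, panel) {
  stopifnot(nrow(conc) == length(site_id))
  if (anyDuplicated(site_id)) stop("duplicate site_id", call. = FALSE)
  unknown <- setdiff(colnames(conc), panel$compound_id)
  if (length(unknown)) {
    stop("compounds not on the panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(site_id = as.character(site_id), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(panel))) {
    cid <- panel$compound_id[k]
    v <- if (cid %in% colnames(conc)) conc[, cid] else rep(NA_real_, length(site_id))
    out[[cid]] <- censor_below_loq(v, panel$loq[k])
  }
  class(out) <- c("residue_samples", "data.frame")
  out
}

#' Nearest-rank quantile
#'
#' The p-th quantile as the ceiling(p * n)-th smallest value, the
#' convention used for the 90th-percentile concentration summaries.
#'
#' @param x Numeric vector (no NAs).
#' @param p Probability in (0, 1].
#' @return The nearest-rank quantile of `x`.
#' @export
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) > 0L, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' Per-compound detection summaries
#'
#' Detection frequency and concentration statistics over the positive
#' (quantified) samples only: mean, median and 90th percentile
#' (nearest-rank). Compounds with no detection keep `NA` statistics.
#'
#' @param samples A `residue_samples` data frame.
#' @param panel A `residue_panel`.
#' @return Data frame with one row per panel compound: `compound_id`,
#'   `n_detect`, `n_sites`, `conc_mean`, `conc_median`, `conc_p90`.
#' @export
compound_summaries <- function(samples, panel) {
  if (nrow(samples) == 0L) stop("no residue samples", call. = FALSE)
  rows <- lapply(panel$compound_id, function(cid) {
    v <- samples[[cid]]
    pos <- v[v > 0]
    data.frame(
      compound_id = cid,
      n_detect = length(pos),
      n_sites = nrow(samples),
      conc_mean = if (length(pos)) mean(pos) else NA_real_,
      conc_median = if (length(pos)) stats::median(pos) else NA_real_,
      conc_p90 = if (length(pos)) nearest_rank_quantile(pos, 0.9) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
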