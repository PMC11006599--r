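#' Toxicity database: per-compound LD50 reduction
#'
#' Pesticide risk weighting needs a single acute toxicity endpoint per
#' compound: the honey-bee (adult *Apis mellifera*) LD50 in micrograms per
#' bee, averaged over the oral and contact exposure routes and taken as the
#' worst case (minimum, i.e. most toxic) across the 24, 48 and 72 h
#' observation time points. Limit-test values reported as "greater than" a
#' dose are rounded down to the stated bound before averaging, and the
#' resulting record is flagged so downstream reports can carry the
#' provenance.
#'
#' @name toxicity_db
NULL

.tox_routes <- c("oral", "contact")
.tox_times <- c(24L, 48L, 72L)
.tox_types <- c("insecticide", "fungicide", "herbicide", "other")
.tox_qualifiers <- c("exact", "greater_than")

#' Worst-case LD50 across observation times
#'
#' Reduces the available time-resolved LD50 values of one exposure route to
#' the single worst case: the minimum dose (most toxic) across whichever of
#' the 24, 48 and 72 h values are present. A value qualified `greater_than`
#' (a limit test that only bounds the LD50 from below) is first rounded down
#' to its stated bound, i.e. taken at face value.
#'
#' @param values Named numeric vector of LD50 doses (ug per bee), names in
#'   `c("24","48","72")` (hours). Partial maps are allowed.
#' @param qualifiers Character vector parallel to `values`, each `"exact"` or
#'   `"greater_than"`. Defaults to all `"exact"`.
#' @param compound_id Compound name used in error messages.
#' @return Worst-case dose (ug per bee), with attribute `limit_test = TRUE`
#'   when the winning value came from a limit test.
#' @examples
#' worst_case_ld50(c(`24` = 0.10, `48` = 0.05, `72` = 0.08)) # 0.05
#' worst_case_ld50(c(`48` = 100), qualifiers = "greater_than") # 100
#' @export
worst_case_ld50 <- function(values, qualifiers = NULL, compound_id = "<unknown>") {
  if (is.null(qualifiers)) qualifiers <- rep("exact", length(values))
  stopifnot(length(qualifiers) == length(values))
  keep <- !is.na(values)
  values <- values[keep]
  qualifiers <- qualifiers[keep]
  if (length(values) == 0L) {
    stop("no LD50 values available for compound '", compound_id, "'",
         call. = FALSE)
  }
  if (!all(qualifiers %in% .tox_qualifiers)) {
    stop("unknown LD50 qualifier for compound '", compound_id, "'", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("nonpositive LD50 for compound '", compound_id, "'", call. = FALSE)
  }
  # round-down rule: a ">x" bound is used as x, qualifier then dropped
  i <- which.min(values)
  structure(unname(values[i]), limit_test = qualifiers[i] == "greater_than")
}

#' Effective LD50 of a compound
#'
#' The single toxicity endpoint used for risk weighting: the arithmetic mean
#' of the worst-case oral and worst-case contact LD50. When only one route
#' has data that route's worst case is used alone, so that compounds with an
#' incomplete database entry can still be scored.
#'
#' @param record A list with elements `oral` and/or `contact` (named dose
#'   vectors, names = hours), optional `oral_qualifiers`,
#'   `contact_qualifiers` (parallel character vectors) and `compound_id`.
#' @return Effective dose (ug per bee); attribute `limit_test` is `TRUE` when
#'   any contributing route value was a rounded-down limit-test bound.
#' @export
effective_ld50 <- function(record) {
  cid <- record$compound_id %||% "<unknown>"
  per_route <- list()
  for (route in .tox_routes) {
    v <- record[[route]]
    if (!is.null(v) && length(v[!is.na(v)]) > 0L) {
      per_route[[route]] <- worst_case_ld50(
        v, record[[paste0(route, "_qualifiers")]], compound_id = cid)
    }
  }
  if (length(per_route) == 0L) {
    stop("no oral or contact LD50 for compound '", cid, "'", call. = FALSE)
  }
  out <- mean(vapply(per_route, as.numeric, 0))
  structure(out, limit_test = any(vapply(per_route, attr, TRUE, "limit_test")))
}

#' Load a long-format toxicity table
#'
#' Reads a CSV with one row per compound x route x time point and reduces it
#' to one record per compound with the effective LD50 precomputed. The
#' packaged fixture `ld50_top10.csv` holds the ten compounds that dominate
#' mixture risk in European bumble-bee pollen stores, with effective mean
#' LD50 values as sourced from the Pesticide Properties Database.
#'
#' @param path CSV with header
#'   `compound_id,pesticide_type,chemical_group,route,time_h,ld50_ug_per_bee,qualifier,loq_ug_per_kg`.
#' @return A data frame of class `toxicity_db`, one row per compound, columns
#'   `compound_id`, `pesticide_type`, `chemical_group`, `ld50` (effective,
#'   ug per bee), `limit_test` (logical), `loq` (ug per kg), `n_routes`,
#'   plus list columns `oral` and `contact` holding the raw time-resolved
#'   doses.
#' @export
load_toxicity_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("compound_id", "pesticide_type", "chemical_group", "route",
              "time_h", "ld50_ug_per_bee", "qualifier", "loq_ug_per_kg")
  if (!all(needed %in% names(raw))) {
    stop("toxicity table is missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(raw$ld50_ug_per_bee) || !is.numeric(raw$loq_ug_per_kg)) {
    stop("non-numeric LD50 or LOQ column in toxicity table", call. = FALSE)
  }
  bad <- which(!(raw$time_h %in% .tox_times))
  if (length(bad)) {
    stop("toxicity table row ", bad[1],
         ": time point must be 24, 48 or 72 h (got ", raw$time_h[bad[1]], ")",
         call. = FALSE)
  }
  bad <- which(!(raw$route %in% .tox_routes))
  if (length(bad)) {
    stop("toxicity table row ", bad[1], ": unknown route '",
         raw$route[bad[1]], "'", call. = FALSE)
  }
  bad <- which(!(raw$qualifier %in% .tox_qualifiers))
  if (length(bad)) {
    stop("toxicity table row ", bad[1], ": unknown qualifier '",
         raw$qualifier[bad[1]], "'", call. = FALSE)
  }
  bad <- which(!is.finite(raw$ld50_ug_per_bee) | raw$ld50_ug_per_bee <= 0)
  if (length(bad)) {
    stop("toxicity table row ", bad[1], ": LD50 must be strictly positive",
         call. = FALSE)
  }
  bad <- which(!is.finite(raw$loq_ug_per_kg) | raw$loq_ug_per_kg <= 0)
  if (length(bad)) {
    stop("toxicity table row ", bad[1], ": LOQ must be strictly positive",
         call. = FALSE)
  }
  dup <- duplicated(raw[, c("compound_id", "route", "time_h")])
  if (any(dup)) {
    stop("duplicate compound/route/time entry for '",
         raw$compound_id[which(dup)[1]], "'", call. = FALSE)
  }
  if (!all(raw$pesticide_type %in% .tox_types)) {
    stop("pesticide_type must be one of ",
         paste(.tox_types, collapse = ", "), call. = FALSE)
  }

  ids <- unique(raw$compound_id)
  rec_one <- function(id) {
    rows <- raw[raw$compound_id == id, , drop = FALSE]
    if (length(unique(rows$loq_ug_per_kg)) > 1L) {
      stop("conflicting LOQ values for compound '", id, "'", call. = FALSE)
    }
    rec <- list(compound_id = id)
    for (route in .tox_routes) {
      rr <- rows[rows$route == route, , drop = FALSE]
      if (nrow(rr)) {
        rec[[route]] <- stats::setNames(rr$ld50_ug_per_bee, rr$time_h)
        rec[[paste0(route, "_qualifiers")]] <- rr$qualifier
      }
    }
    eff <- effective_ld50(rec)
    data.frame(
      compound_id = id,
      pesticide_type = rows$pesticide_type[1],
      chemical_group = rows$chemical_group[1],
      ld50 = as.numeric(eff),
      limit_test = attr(eff, "limit_test"),
      loq = rows$loq_ug_per_kg[1],
      n_routes = sum(.tox_routes %in% rows$route),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(ids, rec_one))
  rownames(out) <- NULL
  class(out) <- c("toxicity_db", class(out))
  out
}

#' Packaged reference toxicity table
#'
#' Convenience loader for the shipped ten-compound fixture (effective mean
#' honey-bee LD50s and LOQs for the highest-risk compounds found in
#' bumble-bee pollen stores).
#'
#' @return A `toxicity_db` data frame; see [load_toxicity_table()].
#' @export
reference_toxicity <- function() {
  load_toxicity_table(
    system.file("extdata", "ld50_top10.csv", package = "pollenrisk",
                mustWork = TRUE))
}

#' Packaged reference residue summary
#'
#' Per-compound summary statistics (mean/median/90th-percentile
#' concentration over positive samples, number of detecting sites out of
#' 106) for the ten compounds of [reference_toxicity()], as observed in a
#' European survey of bumble-bee colony pollen stores.
#'
#' @return Data frame with columns `compound_id`, `conc_mean`, `conc_median`,
#'   `conc_p90`, `n_detect`, `n_sites`.
#' @export
reference_residue_summary <- function() {
  utils::read.csv(
    system.file("extdata", "pollen_survey_top10.csv", package = "pollenrisk",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
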