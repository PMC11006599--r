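#' Colony performance endpoints
#'
#' Sentinel colonies are weighed before deployment (g_initial) and up to
#' three times in the field; cocoons are counted by caste at termination.
#' Endpoints: weight gain as the log response ratio ln(g_max / g_initial),
#' total production as the sum of intact and eclosed cocoons of all castes,
#' and queen production as the intact + eclosed queen cocoons.
#'
#' @name colony_endpoints
NULL

#' Maximum field weight of a colony
#'
#' @param weights Ordered field weighings in grams (earliest first), `NA`
#'   for weighings that did not happen. At least one non-missing weight is
#'   required; all must be positive.
#' @return The maximum weight, with attribute `index` giving which weighing
#'   achieved it; ties resolve to the latest weighing (the colony is taken
#'   to still be at its peak).
#' @export
max_weight <- function(weights) {
  w <- as.numeric(weights)
  ok <- which(!is.na(w))
  if (!length(ok)) {
    stop("colony has no field weighings (exclude it)", call. = FALSE)
  }
  if (any(w[ok] <= 0)) stop("field weights must be positive", call. = FALSE)
  m <- max(w[ok])
  idx <- max(which(!is.na(w) & w == m))
  structure(m, index = idx)
}

#' Log response ratio of colony weight gain
#'
#' @param g_initial Pre-deployment weight, g (> 0).
#' @param g_max Maximum field weight, g (> 0).
#' @return `ln(g_max / g_initial)`; negative for colonies that lost weight.
#'   `exp()` of the result is the proportional weight change.
#' @examples
#' weight_gain_lnrr(500, 1000) # log(2)
#' @export
weight_gain_lnrr <- function(g_initial, g_max) {
  if (any(g_initial <= 0) || any(g_max <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  log(g_max / g_initial)
}

#' Total colony production
#'
#' @param intact_workermale,eclosed_workermale,intact_queen,eclosed_queen
#'   Nonnegative cocoon counts (eclosed cocoons reused for nectar/pollen
#'   storage are already included in the eclosed counts).
#' @return Sum of the four counts.
#' @export
total_production <- function(intact_workermale, eclosed_workermale,
                             intact_queen, eclosed_queen) {
  counts <- cbind(intact_workermale, eclosed_workermale,
                  intact_queen, eclosed_queen)
  if (any(counts < 0)) stop("cocoon counts must be nonnegative", call. = FALSE)
  as.integer(rowSums(counts))
}

#' Queen cocoon production
#'
#' @param intact_queen,eclosed_queen Nonnegative queen cocoon counts.
#' @return `intact_queen + eclosed_queen`, an index of colony reproduction
#'   (zero-inflated in the field: many colonies never reach queen rearing).
#' @export
queen_production <- function(intact_queen, eclosed_queen) {
  if (any(intact_queen < 0) || any(eclosed_queen < 0)) {
    stop("cocoon counts must be nonnegative", call. = FALSE)
  }
  as.integer(intact_queen + eclosed_queen)
}

#' Assemble the colony-level analysis table
#'
#' Joins colony records to their site's mixture risk and landscape
#' covariates, derives the endpoints, excludes colonies whose status is not
#' `"ok"` (losses, insufficient stored pollen) and prepares the model
#' covariates: risk as ln(TWC_mix + offset) centred over the included
#' colonies, cropland proportion centred likewise, initial weight centred.
#' Exclusion therefore never changes an included colony's raw values, only
#' the centring means.
#'
#' @param colonies Data frame with columns `colony_id`, `site_id`,
#'   `g_initial`, `weight_1`..`weight_3` (field weighings, g, `NA` allowed),
#'   `intact_workermale`, `eclosed_workermale`, `intact_queen`,
#'   `eclosed_queen`, `status` (`ok` / `lost` / `insufficient_pollen`) and
#'   optionally `status_reason`.
#' @param risk A `risk_profile` data frame from [risk_profiles()] (one row
#'   per site).
#' @param sites Data frame with `site_id`, `country`, `crop` (`apple` /
#'   `oilseed_rape`), `cropland` (proportion in a 1 km radius).
#' @param offset Log offset for the risk transform (default 0.1).
#' @return Data frame of class `analysis_table`, one row per included
#'   colony: ids, `country`, `crop` (factor, apple reference), `g_initial`,
#'   `g_max`, `gmax_weighing`, `lnrr`, `total_production`,
#'   `queen_production`, `twc_mix`, raw `cropland`, and centred covariates
#'   `risk_c`, `cropland_c`, `g_initial_c`. Attributes: `risk_covariate`
#'   (the [prepare_risk_covariate()] object), `cropland_mean`,
#'   `cropland_sd`, `g_initial_mean`, and `exclusions` (a data frame of
#'   excluded colonies with reasons).
#' @export
build_analysis_table <- function(colonies, risk, sites, offset = 0.1) {
  need <- c("colony_id", "site_id", "g_initial", "intact_workermale",
            "eclosed_workermale", "intact_queen", "eclosed_queen", "status")
  miss <- setdiff(need, names(colonies))
  if (length(miss)) {
    stop("colony table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  excl <- colonies$status != "ok"
  exclusions <- data.frame(
    colony_id = colonies$colony_id[excl],
    site_id = colonies$site_id[excl],
    reason = if ("status_reason" %in% names(colonies))
      colonies$status_reason[excl] else colonies$status[excl],
    stringsAsFactors = FALSE)
  inc <- colonies[!excl, , drop = FALSE]
  if (nrow(inc) == 0L) stop("no colonies left after exclusions", call. = FALSE)

  orphan <- setdiff(unique(inc$site_id), risk$site_id)
  if (length(orphan)) {
    stop("no risk profile for site(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(unique(inc$site_id), sites$site_id)
  if (length(orphan)) {
    stop("no site metadata for site(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }

  wcols <- intersect(c("weight_1", "weight_2", "weight_3"), names(inc))
  gmax <- t(apply(inc[, wcols, drop = FALSE], 1, function(w) {
    m <- max_weight(w); c(m, attr(m, "index"))
  }))

  si <- match(inc$site_id, sites$site_id)
  ri <- match(inc$site_id, risk$site_id)
  out <- data.frame(
    colony_id = inc$colony_id,
    site_id = inc$site_id,
    country = as.character(sites$country[si]),
    crop = factor(as.character(sites$crop[si]),
                  levels = c("apple", "oilseed_rape")),
    g_initial = inc$g_initial,
    g_max = gmax[, 1],
    gmax_weighing = as.integer(gmax[, 2]),
    lnrr = weight_gain_lnrr(inc$g_initial, gmax[, 1]),
    total_production = total_production(
      inc$intact_workermale, inc$eclosed_workermale,
      inc$intact_queen, inc$eclosed_queen),
    queen_production = queen_production(inc$intact_queen, inc$eclosed_queen),
    twc_mix = risk$twc_mix[ri],
    cropland = sites$cropland[si],
    stringsAsFactors = FALSE)

  rc <- prepare_risk_covariate(out$twc_mix, offset = offset)
  out$risk_c <- rc$values
  out$cropland_c <- out$cropland - mean(out$cropland)
  out$g_initial_c <- out$g_initial - mean(out$g_initial)
  rownames(out) <- NULL
  structure(out,
            risk_covariate = rc,
            cropland_mean = mean(out$cropland),
            cropland_sd = stats::sd(out$cropland),
            g_initial_mean = mean(out$g_initial),
            exclusions = exclusions,
            class = c("analysis_table", "data.frame"))
}
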