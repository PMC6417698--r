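# Aquatic effects side: chronic toxicity screening, species-level
# aggregation, species sensitivity distribution fitting, HC5 and PNEC.

#' Chronic toxicity screening rules
#'
#' The default rules admit the chronic endpoints NOEC, MATC and LOEC and
#' require a minimum exposure duration of 1 day for algae and
#' invertebrates and 4 days for crustaceans, fish, mollusks and worms.
#'
#' @param min_duration Named numeric vector of per-group duration floors
#'   (days), covering all six functional groups.
#' @param endpoints Allowed endpoints, a subset of NOEC/MATC/LOEC.
#' @return List of class `screening_rules`.
#' @export
default_screening_rules <- function(
    min_duration = c(algae = 1, invertebrates = 1, crustaceans = 4,
                     fish = 4, mollusks = 4, worms = 4),
    endpoints = c("NOEC", "MATC", "LOEC")) {
  if (!setequal(names(min_duration), FUNCTIONAL_GROUPS)) {
    stop("screening rules must state a duration floor for every group")
  }
  if (any(min_duration <= 0)) stop("duration floors must be > 0")
  endpoints <- match.arg(endpoints, ENDPOINTS, several.ok = TRUE)
  structure(list(min_duration = min_duration, endpoints = endpoints),
            class = "screening_rules")
}

#' Screen chronic toxicity records
#'
#' Keeps records whose endpoint is allowed and whose exposure duration
#' meets the functional-group-specific floor. The counts removed by each
#' rule are attached as the `"screen_log"` attribute and reported via
#' `message()`. An empty result is allowed but warned about.
#'
#' @param records Validated toxicity records ([read_toxicity()] layout).
#' @param rules A [default_screening_rules()] object.
#' @return The filtered data.frame, with attribute `screen_log`.
#' @export
screen_toxicity <- function(records, rules = default_screening_rules()) {
  ep_ok <- records$endpoint %in% rules$endpoints
  floor_days <- rules$min_duration[records$functional_group]
  dur_ok <- records$duration_days >= floor_days
  keep <- ep_ok & dur_ok
  log <- c(removed_endpoint = sum(!ep_ok),
           removed_duration = sum(ep_ok & !dur_ok),
           kept = sum(keep))
  message("screen_toxicity: kept ", log[["kept"]], "/", nrow(records),
          " records (", log[["removed_endpoint"]], " endpoint, ",
          log[["removed_duration"]], " duration removals)")
  if (log[["kept"]] == 0) warning("screen_toxicity: no records survived")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screen_log") <- log
  out
}

#' Aggregate toxicity records to one tolerance per species
#'
#' Multiple chronic records for the same species are collapsed to a single
#' species tolerance before SSD fitting. The default policy is the
#' geometric mean (standard SSD practice); `"minimum"` takes the most
#' sensitive record. The policy used is recorded in the output's
#' `"aggregation_policy"` attribute so results stay auditable.
#'
#' @param records Screened toxicity records of a single metal.
#' @param policy `"geometric_mean"` (default) or `"minimum"`.
#' @return data.frame `species, functional_group, tolerance_ugL,
#'   n_records`, one row per species.
#' @export
aggregate_by_species <- function(records,
                                 policy = c("geometric_mean", "minimum")) {
  policy <- match.arg(policy)
  if (length(unique(records$metal)) > 1) {
    stop("aggregate_by_species: records span more than one metal")
  }
  f <- if (policy == "geometric_mean") geometric_mean else min
  sp <- split(records, records$species)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(species = d$species[1],
               functional_group = d$functional_group[1],
               tolerance_ugL = f(d$value_ugL),
               n_records = nrow(d))
  }))
  rownames(out) <- NULL
  attr(out, "aggregation_policy") <- policy
  out
}

#' Fit a species sensitivity distribution and derive HC5
#'
#' Fits the candidate families to species tolerances and selects by the
#' Anderson-Darling p-value with AIC as tie-breaker (the tail-weighted
#' criterion appropriate when the 5th percentile is the target). Data
#' adequacy is enforced first: at least 8 species spanning at least 3
#' functional groups (the functional-group approximation of the "eight
#' families in three classes" adequacy convention).
#'
#' @param tolerances Species tolerance concentrations, ug/L.
#' @param groups Functional group of each species (same length).
#' @param metal Optional metal code carried into the result.
#' @param families Candidate families, default all of [dist_families()].
#' @param ad_B Anderson-Darling bootstrap resamples for selection.
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `ssd_model`: list with `metal`, `fitted` (the
#'   winning [risk_dist()]), `ranking`, `n_species`, `hc5` (ug/L, the 5th
#'   percentile of the fitted SSD) and `gof` (the winning family's ranking
#'   row).
#' @export
fit_ssd <- function(tolerances, groups, metal = NA_character_,
                    families = dist_families(), ad_B = 199, seed = NULL) {
  stopifnot(length(tolerances) == length(groups))
  n_sp <- length(tolerances)
  n_gr <- length(unique(groups))
  if (n_sp < 8 || n_gr < 3) {
    stop("fit_ssd: inadequate data (", n_sp, " species in ", n_gr,
         " functional groups; need >= 8 species in >= 3 groups)")
  }
  sel <- select_model(tolerances, families = families,
                      criterion = "ad_p_aic", ad_B = ad_B, seed = seed)
  hc5 <- dist_quantile(sel$best, 0.05)
  structure(
    list(metal = metal, fitted = sel$best, ranking = sel$ranking,
         n_species = n_sp, n_records = n_sp, hc5 = hc5,
         gof = sel$ranking[sel$ranking$family == sel$best$family, ]),
    class = "ssd_model"
  )
}

#' @export
print.ssd_model <- function(x, ...) {
  cat("<ssd_model>", if (!is.na(x$metal)) x$metal else "", "- family:",
      x$fitted$family, "\n")
  cat("  n_species:", x$n_species, " HC5:", signif(x$hc5, 4), "ug/L\n")
  invisible(x)
}

#' Predicted no-effect concentration
#'
#' `PNEC = HC5 / safety_factor` (default factor 5), ug/L.
#'
#' @param hc5 HC5 in ug/L (> 0).
#' @param safety_factor Dimensionless assessment factor (> 0), default 5.
#' @return PNEC in ug/L.
#' @examples
#' pnec(9.33)  # 1.866
#' @export
pnec <- function(hc5, safety_factor = 5) {
  if (any(hc5 <= 0) || safety_factor <= 0) {
    stop("pnec: hc5 and safety_factor must be > 0")
  }
  hc5 / safety_factor
}
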