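# Pipeline orchestration and report tables. The three stages mirror how
# the assessment is run in practice: simulate (or load) a survey, assess
# the sediment track, assess the aquatic track. Every stochastic stage
# takes an explicit seed and the reports record it.

#' Simulate a survey and write its files
#'
#' Generates the concentration and toxicity tables of a scenario and
#' writes `concentrations.csv`, `toxicity.csv`, the scenario as
#' `scenario.yaml` and a small provenance log (seed and file checksums).
#' Reruns with the same seed and scenario produce identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param scenario A [laizhou_scenario()]-style scenario.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_survey <- function(out_dir, seed = 1,
                            scenario = laizhou_scenario()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conc <- gen_concentrations(scenario, seed = seed)
  tox <- gen_toxicity(scenario, seed = seed + 1)
  paths <- list(
    concentrations = file.path(out_dir, "concentrations.csv"),
    toxicity = file.path(out_dir, "toxicity.csv"),
    scenario = file.path(out_dir, "scenario.yaml"),
    log = file.path(out_dir, "run_log.txt")
  )
  write_concentrations(conc, paths$concentrations)
  write_toxicity(tox, paths$toxicity)
  write_scenario(scenario, paths$scenario)
  sums <- tools::md5sum(unlist(paths[1:3]))
  writeLines(c(
    paste("seed:", seed),
    paste("records:", nrow(conc), "concentration,", nrow(tox), "toxicity"),
    paste(basename(names(sums)), unname(sums))
  ), paths$log)
  invisible(paths)
}

#' Sediment-track assessment
#'
#' Per season and metal: collapses replicates to station values, fits the
#' candidate families and selects by the Kolmogorov-Smirnov criterion,
#' computes the average risk factor from the mean concentration, and runs
#' the Monte Carlo grade-probability refinement. Per season it also sums
#' the average risk factors into RI and runs the Monte Carlo RI
#' refinement.
#'
#' @param records Sediment concentration records (data.frame or a CSV
#'   path).
#' @param ref Reference table.
#' @param n_draws Monte Carlo draws per metal (default 100000).
#' @param seed Integer seed.
#' @param combine Replicate policy for [combine_replicates()].
#' @param families Candidate families for the exposure fits.
#' @return List of class `sediment_assessment`: `eri_table` (one row per
#'   season x metal with the mean concentration, selected family, average
#'   Eri, grade and the five grade-probability columns), `ri_table` (one
#'   row per season with average RI, grade and the four RI grade
#'   probabilities), `fits`, `mc` and `seed`.
#' @export
assess_sediment <- function(records, ref = default_reference(),
                            n_draws = 100000, seed = 1,
                            combine = c("station_mean", "pooled"),
                            families = dist_families()) {
  combine <- match.arg(combine)
  if (is.character(records)) records <- read_concentrations(records)
  records <- records[records$matrix == "sediment", , drop = FALSE]
  if (nrow(records) == 0) stop("assess_sediment: no sediment records")
  stations <- combine_replicates(records, combine)

  eri_rows <- list(); ri_rows <- list(); fits <- list(); mc <- list()
  for (season in unique(stations$season)) {
    season_eris <- list()
    for (m in intersect(metals(), unique(stations$metal))) {
      v <- stations$value[stations$season == season & stations$metal == m]
      if (length(v) < 3) {
        stop("assess_sediment: fewer than 3 stations for ", m, " in ",
             season)
      }
      sel <- select_model(v, families = families, criterion = "ks_p")
      point <- eri(mean(v), m, ref)
      dist_mc <- mc_eri(sel$best, m, ref, n_draws = n_draws,
                        seed = seed + match(m, metals()))
      key <- paste(season, m, sep = ".")
      fits[[key]] <- sel
      mc[[key]] <- dist_mc
      season_eris[[m]] <- point
      eri_rows[[key]] <- cbind(
        data.frame(season = season, metal = m, n_stations = length(v),
                   mean_conc = mean(v), family = sel$best$family,
                   avg_eri = point$eri, grade = point$grade),
        as.data.frame(as.list(dist_mc$grade_probabilities))
      )
    }
    point_ri <- ri(do.call(rbind, season_eris))
    mc_index <- mc_ri(lapply(stats::setNames(metals(), metals()),
                             function(m) fits[[paste(season, m, sep = ".")]]$best),
                      ref, n_draws = n_draws, seed = seed + 100)
    mc[[paste(season, "RI", sep = ".")]] <- mc_index
    ri_rows[[season]] <- cbind(
      data.frame(season = season, avg_ri = point_ri$ri,
                 grade = point_ri$grade),
      as.data.frame(as.list(mc_index$grade_probabilities))
    )
  }
  structure(
    list(eri_table = do.call(rbind, c(eri_rows, make.row.names = FALSE)),
         ri_table = do.call(rbind, c(ri_rows, make.row.names = FALSE)),
         fits = fits, mc = mc, seed = seed),
    class = "sediment_assessment"
  )
}

#' Aquatic-track assessment
#'
#' Effects side: per metal, screens the chronic toxicity records,
#' aggregates them to one tolerance per species, fits the species
#' sensitivity distribution (Anderson-Darling + AIC selection) and derives
#' HC5 and PNEC. Exposure side: per season and metal, collapses seawater
#' replicates to station values, computes the EEC (geometric mean by
#' default) and the hazard quotient, fits the exposure distribution
#' (Kolmogorov-Smirnov selection), and integrates the joint probability
#' curve into the overall risk probability.
#'
#' @param seawater Seawater concentration records (data.frame or CSV
#'   path).
#' @param toxicity Toxicity records (data.frame or CSV path).
#' @param ref Reference table (supplies the safety factor).
#' @param rules Screening rules.
#' @param seed Integer seed (drives the Anderson-Darling bootstrap).
#' @param grid_size JPC grid size.
#' @param eec_policy `"geometric"` (default) or `"arithmetic"` mean EEC.
#' @param agg_policy Species aggregation policy, see
#'   [aggregate_by_species()].
#' @param combine Replicate policy.
#' @param ad_B Anderson-Darling bootstrap resamples.
#' @param metals_subset Optional subset of metals to assess.
#' @param families Candidate families.
#' @return List of class `aquatic_assessment`: `ssd_table` (metal,
#'   n_species, selected family, HC5, PNEC), `risk_table` (metal x season:
#'   EEC, HQ and its flag, ORP and its decision), plus the fitted `ssds`,
#'   `exposures` and `jpcs`, and `seed`.
#' @export
assess_aquatic <- function(seawater, toxicity, ref = default_reference(),
                           rules = default_screening_rules(), seed = 1,
                           grid_size = 10001,
                           eec_policy = c("geometric", "arithmetic"),
                           agg_policy = "geometric_mean",
                           combine = c("station_mean", "pooled"),
                           ad_B = 199, metals_subset = NULL,
                           families = dist_families()) {
  eec_policy <- match.arg(eec_policy)
  combine <- match.arg(combine)
  if (is.character(seawater)) seawater <- read_concentrations(seawater)
  if (is.character(toxicity)) toxicity <- read_toxicity(toxicity)
  seawater <- seawater[seawater$matrix == "seawater", , drop = FALSE]
  if (nrow(seawater) == 0) stop("assess_aquatic: no seawater records")
  mets <- intersect(metals(), unique(seawater$metal))
  if (!is.null(metals_subset)) mets <- intersect(mets, metals_subset)
  stations <- combine_replicates(seawater, combine)

  ssds <- list(); ssd_rows <- list()
  for (m in mets) {
    recs <- toxicity[toxicity$metal == m, , drop = FALSE]
    kept <- suppressMessages(screen_toxicity(recs, rules))
    agg <- aggregate_by_species(kept, agg_policy)
    model <- tryCatch(
      fit_ssd(agg$tolerance_ugL, agg$functional_group, metal = m,
              families = families, ad_B = ad_B,
              seed = seed + match(m, metals())),
      error = function(e) {
        stop("assess_aquatic: SSD for ", m, " failed: ",
             conditionMessage(e))
      }
    )
    ssds[[m]] <- model
    ssd_rows[[m]] <- data.frame(
      metal = m, n_records = nrow(kept), n_species = model$n_species,
      family = model$fitted$family, hc5 = model$hc5,
      pnec = pnec(model$hc5, ref$safety_factor)
    )
  }

  exposures <- list(); jpcs <- list(); risk_rows <- list()
  for (season in unique(stations$season)) {
    for (m in mets) {
      v <- stations$value[stations$season == season & stations$metal == m]
      if (length(v) < 3) {
        stop("assess_aquatic: fewer than 3 stations for ", m, " in ",
             season)
      }
      eec <- if (eec_policy == "geometric") geometric_mean(v) else mean(v)
      pn <- pnec(ssds[[m]]$hc5, ref$safety_factor)
      hq <- hazard_quotient(eec, pn)
      sel <- select_model(v, families = families, criterion = "ks_p")
      curve <- jpc(ssds[[m]], sel$best, grid_size = grid_size)
      key <- paste(season, m, sep = ".")
      exposures[[key]] <- sel
      jpcs[[key]] <- curve
      risk_rows[[key]] <- data.frame(
        season = season, metal = m, n_stations = length(v), eec = eec,
        hc5 = ssds[[m]]$hc5, pnec = pn, hq = hq$hq, hq_flag = hq$flag,
        exposure_family = sel$best$family, orp = curve$orp,
        decision = curve$decision
      )
    }
  }
  structure(
    list(ssd_table = do.call(rbind, c(ssd_rows, make.row.names = FALSE)),
         risk_table = do.call(rbind, c(risk_rows, make.row.names = FALSE)),
         ssds = ssds, exposures = exposures, jpcs = jpcs, seed = seed),
    class = "aquatic_assessment"
  )
}

#' Write assessment report tables to CSV
#'
#' `write_sediment_report` writes the season x metal Eri table (average
#' estimation, grade and Monte Carlo grade probabilities), the RI table
#' and the per-stratum model-selection rankings. `write_aquatic_report`
#' writes the SSD table (HC5/PNEC), the per-season risk table (HQ, ORP,
#' decisions) and the SSD rankings.
#'
#' @param assessment A `sediment_assessment` or `aquatic_assessment`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sediment_report <- function(assessment, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    eri = file.path(out_dir, "sediment_eri.csv"),
    ri = file.path(out_dir, "sediment_ri.csv"),
    ranking = file.path(out_dir, "sediment_fit_ranking.csv")
  )
  utils::write.csv(assessment$eri_table, paths[["eri"]], row.names = FALSE)
  utils::write.csv(assessment$ri_table, paths[["ri"]], row.names = FALSE)
  rank <- do.call(rbind, lapply(names(assessment$fits), function(k) {
    cbind(stratum = k, assessment$fits[[k]]$ranking)
  }))
  utils::write.csv(rank, paths[["ranking"]], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_sediment_report
#' @export
write_aquatic_report <- function(assessment, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ssd = file.path(out_dir, "aquatic_ssd.csv"),
    risk = file.path(out_dir, "aquatic_risk.csv"),
    ranking = file.path(out_dir, "aquatic_ssd_ranking.csv")
  )
  utils::write.csv(assessment$ssd_table, paths[["ssd"]], row.names = FALSE)
  utils::write.csv(assessment$risk_table, paths[["risk"]],
                   row.names = FALSE)
  rank <- do.call(rbind, lapply(names(assessment$ssds), function(m) {
    cbind(metal = m, assessment$ssds[[m]]$ranking)
  }))
  utils::write.csv(rank, paths[["ranking"]], row.names = FALSE)
  invisible(paths)
}
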