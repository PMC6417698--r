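# Synthetic survey generator: station concentration tables and chronic
# toxicity datasets with the statistical structure the analysis assumes
# (per-stratum mean/SD/range, station roster, functional-group counts),
# so every pipeline stage runs without any external download.

SEASONS <- c("spring_2016_05", "autumn_2016_09")

dms <- function(d, m, s) d + m / 60 + s / 3600

# Station roster of the emulated bay survey: 20 seawater stations, 10 of
# which also have sediment grabs.
station_roster <- function() {
  data.frame(
    station_id = sprintf("S%02d", 1:20),
    longitude = c(
      dms(119, 7, 34.07), dms(119, 20, 13.70), dms(119, 0, 5.21),
      dms(119, 9, 0.39), dms(119, 15, 37.47), dms(119, 0, 48.36),
      dms(119, 11, 9.88), dms(119, 22, 57.71), dms(118, 55, 3.08),
      dms(119, 0, 13.83), dms(119, 4, 28.48), dms(119, 10, 22.40),
      dms(119, 18, 21.48), dms(119, 2, 14.68), dms(119, 8, 4.29),
      dms(119, 14, 50.00), dms(119, 25, 28.78), dms(119, 6, 7.75),
      dms(119, 12, 49.15), dms(119, 21, 1.18)
    ),
    latitude = c(
      dms(37, 33, 6.75), dms(37, 36, 11.78), dms(37, 28, 25.78),
      dms(37, 30, 2.15), dms(37, 31, 30.81), dms(37, 25, 13.91),
      dms(37, 27, 17.26), dms(37, 29, 44.59), dms(37, 21, 3.78),
      dms(37, 22, 2.02), dms(37, 23, 27.69), dms(37, 24, 49.92),
      dms(37, 26, 29.29), dms(37, 20, 12.38), dms(37, 21, 24.34),
      dms(37, 22, 32.87), dms(37, 24, 25.94), dms(37, 16, 50.22),
      dms(37, 18, 57.00), dms(37, 21, 10.63)
    ),
    has_sediment = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                     TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                     FALSE, FALSE, FALSE, TRUE)
  )
}

conc_row <- function(matrix, season, metal, min, max, mean, sd) {
  data.frame(matrix = matrix, season = season, metal = metal,
             min = min, max = max, mean = mean, sd = sd)
}

#' Default two-season bay survey scenario
#'
#' Packages the survey conditions the generator emulates: per-stratum
#' (matrix x season x metal) concentration range, mean and SD; the station
#' roster (20 seawater stations of which 10 carry sediment grabs, 3
#' replicates each); and, for the toxicity side, the per-metal
#' functional-group record counts together with a true log-logistic SSD
#' per metal whose 5th percentile matches the reported HC5 values of
#' [laizhou_hc5()] (shape fixed at 1.5, a typical breadth for
#' multi-taxon chronic SSDs).
#'
#' @return List of class `risk_scenario` with elements `concentrations`
#'   (stratum table), `stations` (roster), `n_replicates`,
#'   `replicate_cv` (relative SD of within-station replicate jitter),
#'   and `toxicity` (`counts` per group x metal, `ssd` per-metal true
#'   parameters, endpoint mix and duration ranges).
#' @export
laizhou_scenario <- function() {
  sp <- SEASONS[1]; au <- SEASONS[2]
  conc <- rbind(
    # sediment, mg/kg dry weight
    conc_row("sediment", sp, "As", 10.70, 12.70, 11.49, 0.71),
    conc_row("sediment", sp, "Cd", 0.11, 0.18, 0.14, 0.02),
    conc_row("sediment", sp, "Cr", 23.60, 29.80, 26.51, 1.87),
    conc_row("sediment", sp, "Cu", 18.00, 25.50, 21.75, 2.25),
    conc_row("sediment", sp, "Hg", 0.009, 0.016, 0.011, 0.002),
    conc_row("sediment", sp, "Pb", 17.50, 24.60, 20.53, 2.35),
    conc_row("sediment", sp, "Zn", 21.50, 35.50, 27.42, 3.91),
    conc_row("sediment", au, "As", 9.20, 11.90, 10.50, 0.78),
    conc_row("sediment", au, "Cd", 0.16, 0.18, 0.17, 0.01),
    conc_row("sediment", au, "Cr", 31.50, 37.00, 34.30, 1.71),
    conc_row("sediment", au, "Cu", 17.60, 20.50, 19.30, 0.88),
    conc_row("sediment", au, "Hg", 0.022, 0.035, 0.025, 0.005),
    conc_row("sediment", au, "Pb", 13.40, 15.80, 14.80, 0.93),
    conc_row("sediment", au, "Zn", 34.40, 43.50, 39.00, 2.81),
    # seawater, ug/L
    conc_row("seawater", sp, "As", 3.01, 3.87, 3.43, 0.26),
    conc_row("seawater", sp, "Cd", 0.11, 0.19, 0.14, 0.02),
    conc_row("seawater", sp, "Cr", 4.16, 6.17, 5.12, 0.63),
    conc_row("seawater", sp, "Cu", 1.31, 2.96, 2.38, 0.38),
    conc_row("seawater", sp, "Hg", 0.01, 0.04, 0.03, 0.01),
    conc_row("seawater", sp, "Pb", 1.29, 2.87, 1.91, 0.49),
    conc_row("seawater", sp, "Zn", 30.90, 49.80, 40.48, 5.35),
    conc_row("seawater", au, "As", 3.27, 3.84, 3.57, 0.16),
    conc_row("seawater", au, "Cd", 0.16, 0.20, 0.18, 0.01),
    conc_row("seawater", au, "Cr", 4.78, 5.19, 5.01, 0.12),
    conc_row("seawater", au, "Cu", 2.44, 2.82, 2.58, 0.12),
    conc_row("seawater", au, "Hg", 0.02, 0.03, 0.02, 0.002),
    conc_row("seawater", au, "Pb", 1.36, 1.79, 1.58, 0.11),
    conc_row("seawater", au, "Zn", 36.80, 43.60, 39.85, 1.67)
  )
  counts <- data.frame(
    functional_group = FUNCTIONAL_GROUPS,
    As = c(12, 5, 4, 1, 1, 0),
    Cd = c(12, 2, 9, 6, 16, 6),
    Cr = c(16, 10, 3, 4, 3, 2),
    Cu = c(38, 27, 9, 15, 25, 9),
    Hg = c(6, 2, 1, 3, 6, 2),
    Pb = c(8, 6, 1, 1, 11, 2),
    Zn = c(10, 18, 4, 2, 15, 3)
  )
  hc5 <- laizhou_hc5()
  beta <- 1.5
  ssd <- data.frame(
    metal = names(hc5), family = "log_logistic",
    alpha = unname(hc5) * 19^(1 / beta), beta = beta
  )
  structure(
    list(
      concentrations = conc,
      stations = station_roster(),
      n_replicates = 3L,
      replicate_cv = 0.02,
      toxicity = list(
        counts = counts, ssd = ssd,
        endpoint_mix = c(NOEC = 0.7, MATC = 0.15, LOEC = 0.15),
        duration_span_days = 26
      )
    ),
    class = "risk_scenario"
  )
}

validate_scenario <- function(scenario) {
  conc <- scenario$concentrations
  stopifnot(all(c("matrix", "season", "metal", "min", "max", "mean", "sd")
                %in% names(conc)))
  if (any(conc$sd <= 0)) stop("scenario: stratum sd must be > 0")
  if (any(conc$min > conc$mean | conc$mean > conc$max)) {
    stop("scenario: need min <= mean <= max in every stratum")
  }
  invisible(scenario)
}

# Rejection sampling from Normal(mean, sd) truncated to [lo, hi]; errors
# out when the acceptance region is essentially empty.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  accept <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  if (accept < 0.01) {
    stop("rnorm_trunc: infeasible truncation (acceptance ",
         signif(accept, 3), " < 1%)")
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(ceiling((n - length(out)) / accept) + 10, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate station concentration records
#'
#' Draws per-station values from a normal law with each stratum's mean and
#' SD, rejection-truncated to the stratum's observed range, then adds
#' within-station replicate jitter (truncated normal, relative SD
#' `replicate_cv`). Deterministic under a fixed seed.
#'
#' @param scenario A [laizhou_scenario()]-style scenario.
#' @param seed Integer seed.
#' @param matrix,seasons,metals_subset Optional filters restricting which
#'   strata are generated.
#' @return A validated concentration record data.frame in the
#'   `concentrations.csv` schema.
#' @export
gen_concentrations <- function(scenario = laizhou_scenario(), seed = 1,
                               matrix = NULL, seasons = NULL,
                               metals_subset = NULL) {
  validate_scenario(scenario)
  set.seed(seed)
  conc <- scenario$concentrations
  if (!is.null(matrix)) conc <- conc[conc$matrix %in% matrix, ]
  if (!is.null(seasons)) conc <- conc[conc$season %in% seasons, ]
  if (!is.null(metals_subset)) conc <- conc[conc$metal %in% metals_subset, ]
  roster <- scenario$stations
  reps <- seq_len(scenario$n_replicates)
  out <- vector("list", nrow(conc))
  for (i in seq_len(nrow(conc))) {
    s <- conc[i, ]
    st <- if (s$matrix == "sediment") roster[roster$has_sediment, ] else roster
    centers <- rnorm_trunc(nrow(st), s$mean, s$sd, s$min, s$max)
    rows <- lapply(seq_len(nrow(st)), function(j) {
      vals <- rnorm_trunc(length(reps), centers[j],
                          scenario$replicate_cv * centers[j], s$min, s$max)
      data.frame(station_id = st$station_id[j],
                 longitude = st$longitude[j], latitude = st$latitude[j],
                 season = s$season, matrix = s$matrix, metal = s$metal,
                 replicate = reps, value = vals)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_concentrations(res, "<generated>")
  res
}

#' Generate a chronic toxicity dataset
#'
#' Draws one species tolerance per record from each metal's true SSD,
#' assigns records to functional groups according to the scenario counts,
#' and draws exposure durations uniformly above the screening floors (so
#' the default dataset is fully screening-compliant). Endpoint labels are
#' sampled from the scenario's NOEC/MATC/LOEC mix.
#'
#' @inheritParams gen_concentrations
#' @param rules Screening rules supplying the per-group duration floors.
#' @return A validated toxicity record data.frame in the `toxicity.csv`
#'   schema.
#' @export
gen_toxicity <- function(scenario = laizhou_scenario(), seed = 1,
                         metals_subset = NULL,
                         rules = default_screening_rules()) {
  set.seed(seed)
  tox <- scenario$toxicity
  mets <- setdiff(names(tox$counts), "functional_group")
  if (!is.null(metals_subset)) mets <- intersect(mets, metals_subset)
  out <- list()
  for (m in mets) {
    counts <- stats::setNames(tox$counts[[m]], tox$counts$functional_group)
    n <- sum(counts)
    if (n == 0) next
    pars <- tox$ssd[tox$ssd$metal == m, ]
    tol <- rllogis(n, pars$alpha, pars$beta)
    grp <- rep(names(counts), counts)
    floors <- rules$min_duration[grp]
    dur <- floors + stats::runif(n, 0, tox$duration_span_days)
    ep <- sample(names(tox$endpoint_mix), n, replace = TRUE,
                 prob = tox$endpoint_mix)
    out[[m]] <- data.frame(
      species = sprintf("synthetic_%s_%s_%02d", m, grp,
                        stats::ave(seq_len(n), grp, FUN = seq_along)),
      functional_group = grp, metal = m, endpoint = ep,
      duration_days = round(dur, 1), value_ugL = tol
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_toxicity(res, "<generated>")
  res
}

#' Save or load a scenario as structured YAML
#'
#' Round-trips a [laizhou_scenario()]-style scenario through a YAML file,
#' preserving all stratum summaries, the station roster and the toxicity
#' configuration.
#'
#' @param scenario A `risk_scenario` object.
#' @param path File path.
#' @return `write_scenario` the path (invisibly); `read_scenario` the
#'   scenario.
#' @export
write_scenario <- function(scenario, path) {
  obj <- list(
    concentrations = as.list(scenario$concentrations),
    stations = as.list(scenario$stations),
    n_replicates = scenario$n_replicates,
    replicate_cv = scenario$replicate_cv,
    toxicity = list(
      counts = as.list(scenario$toxicity$counts),
      ssd = as.list(scenario$toxicity$ssd),
      endpoint_mix = as.list(scenario$toxicity$endpoint_mix),
      duration_span_days = scenario$toxicity$duration_span_days
    )
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(
    list(
      concentrations = as.data.frame(obj$concentrations),
      stations = as.data.frame(obj$stations),
      n_replicates = as.integer(obj$n_replicates),
      replicate_cv = obj$replicate_cv,
      toxicity = list(
        counts = as.data.frame(obj$toxicity$counts),
        ssd = as.data.frame(obj$toxicity$ssd),
        endpoint_mix = unlist(obj$toxicity$endpoint_mix),
        duration_span_days = obj$toxicity$duration_span_days
      )
    ),
    class = "risk_scenario"
  )
}
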