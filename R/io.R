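# CSV readers/writers and summary statistics for station chemistry and
# chronic toxicity tables. Schemas are enforced strictly: silent column
# drift is the main data-corruption risk in multi-campaign surveys.

#' The seven assessed heavy metals
#'
#' The closed set of metals covered by both the sediment and seawater
#' quality standards the assessment is built around.
#'
#' @return Character vector: As, Cd, Cr, Cu, Hg, Pb, Zn.
#' @export
metals <- function() c("As", "Cd", "Cr", "Cu", "Hg", "Pb", "Zn")

FUNCTIONAL_GROUPS <- c("algae", "crustaceans", "fish", "invertebrates",
                       "mollusks", "worms")
ENDPOINTS <- c("NOEC", "MATC", "LOEC")
MATRICES <- c("sediment", "seawater")

CONC_COLUMNS <- c("station_id", "longitude", "latitude", "season", "matrix",
                  "metal", "replicate", "value")
TOX_COLUMNS <- c("species", "functional_group", "metal", "endpoint",
                 "duration_days", "value_ugL")

check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }
}

#' Read a station concentration table
#'
#' Reads `concentrations.csv` (columns `station_id, longitude, latitude,
#' season, matrix, metal, replicate, value`). Units are fixed by the
#' matrix: mg/kg dry weight for sediment, ug/L for seawater; no conversion
#' is ever applied. Malformed rows are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param matrix Optional `"sediment"` or `"seawater"`: subset to that
#'   matrix after validation.
#' @return A data.frame of validated records with a `units` column.
#' @export
read_concentrations <- function(path, matrix = NULL) {
  if (!file.exists(path)) stop("read_concentrations: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, CONC_COLUMNS, path)
  validate_concentrations(df, path)
  if (!is.null(matrix)) {
    matrix <- match.arg(matrix, MATRICES)
    df <- df[df$matrix == matrix, , drop = FALSE]
  }
  df$units <- ifelse(df$matrix == "sediment", "mg/kg dw", "ug/L")
  rownames(df) <- NULL
  df
}

validate_concentrations <- function(df, path = "<data>") {
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- !df$matrix %in% MATRICES
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": unknown matrix '",
         df$matrix[which(bad)[1]], "'")
  }
  bad <- !df$metal %in% metals()
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": unknown metal code '",
         df$metal[which(bad)[1]], "'")
  }
  bad <- !is.finite(df$value) | df$value <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop("validation error in '", path, "', line ", line[i],
         ": non-positive value for station '", df$station_id[i],
         "', metal ", df$metal[i])
  }
  bad <- !is.finite(df$replicate) | df$replicate < 1
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": replicate must be >= 1")
  }
  key <- paste(df$station_id, df$season, df$matrix, df$metal, df$replicate)
  if (anyDuplicated(key)) {
    stop("validation error in '", path, "': duplicate (station, season, ",
         "matrix, metal, replicate) key at line ",
         line[which(duplicated(key))[1]])
  }
  invisible(df)
}

#' @rdname read_concentrations
#' @param records A concentration record data.frame.
#' @export
write_concentrations <- function(records, path) {
  utils::write.csv(records[, CONC_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a chronic toxicity table
#'
#' Reads `toxicity.csv` (columns `species, functional_group, metal,
#' endpoint, duration_days, value_ugL`). Functional groups and endpoints
#' are closed sets: only the six marine functional groups and the chronic
#' endpoints NOEC, MATC and LOEC are admitted — acute endpoints such as
#' EC50 are rejected at parse time.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of validated toxicity records.
#' @export
read_toxicity <- function(path) {
  if (!file.exists(path)) stop("read_toxicity: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, TOX_COLUMNS, path)
  validate_toxicity(df, path)
  rownames(df) <- NULL
  df
}

validate_toxicity <- function(df, path = "<data>") {
  line <- seq_len(nrow(df)) + 1L
  bad <- !df$functional_group %in% FUNCTIONAL_GROUPS
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": unknown functional group '",
         df$functional_group[which(bad)[1]], "'")
  }
  bad <- !df$endpoint %in% ENDPOINTS
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": endpoint '",
         df$endpoint[which(bad)[1]], "' is not a chronic endpoint (",
         paste(ENDPOINTS, collapse = "/"), ")")
  }
  bad <- !df$metal %in% metals()
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": unknown metal code")
  }
  bad <- !is.finite(df$value_ugL) | df$value_ugL <= 0
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": value_ugL must be > 0")
  }
  bad <- !is.finite(df$duration_days) | df$duration_days <= 0
  if (any(bad)) {
    stop("validation error in '", path, "', line(s) ",
         paste(line[bad], collapse = ", "), ": duration_days must be > 0")
  }
  invisible(df)
}

#' @rdname read_toxicity
#' @param records A toxicity record data.frame.
#' @export
write_toxicity <- function(records, path) {
  utils::write.csv(records[, TOX_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Collapse replicate measurements to one value per station
#'
#' Field campaigns take several grabs per station; how they are combined
#' before distribution fitting is a modelling choice. The default averages
#' replicates within a station; `"pooled"` keeps every replicate as its
#' own observation.
#'
#' @param records Concentration records (one matrix/season/metal stratum or
#'   several; grouping keys are respected).
#' @param policy `"station_mean"` (default) or `"pooled"`.
#' @return A data.frame with one row per station (or per replicate under
#'   `"pooled"`) carrying `station_id, season, matrix, metal, value`.
#' @export
combine_replicates <- function(records, policy = c("station_mean", "pooled")) {
  policy <- match.arg(policy)
  if (policy == "pooled") {
    return(records[, c("station_id", "season", "matrix", "metal", "value")])
  }
  agg <- stats::aggregate(
    value ~ station_id + season + matrix + metal, data = records, FUN = mean
  )
  agg[order(agg$season, agg$matrix, agg$metal, agg$station_id), ,
      drop = FALSE]
}

#' Summary statistics for one concentration stratum
#'
#' Computes `n`, minimum, maximum, arithmetic mean and sample standard
#' deviation (n - 1 denominator) of the values of a single
#' (matrix, metal, season) stratum. A single observation has `sd = 0` by
#' convention.
#'
#' @param records Concentration records of exactly one stratum.
#' @return A one-row data.frame: `n, minimum, maximum, mean, sd`.
#' @export
summarize_concentrations <- function(records) {
  if (nrow(records) == 0) stop("summarize_concentrations: empty input")
  strata <- unique(records[, c("matrix", "metal", "season")])
  if (nrow(strata) > 1) {
    stop("summarize_concentrations: mixed strata; summarize one ",
         "(matrix, metal, season) combination at a time")
  }
  v <- records$value
  data.frame(
    n = length(v), minimum = min(v), maximum = max(v), mean = mean(v),
    sd = if (length(v) == 1) 0 else stats::sd(v)
  )
}

#' Geometric mean
#'
#' `exp(mean(log(x)))`; never exceeds the arithmetic mean. Used as the
#' default summary of seawater exposure concentrations.
#'
#' @param x Strictly positive values.
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(2, 8))  # 4
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0) stop("geometric_mean: empty input")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric_mean: all values must be finite and > 0")
  }
  exp(mean(log(x)))
}
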