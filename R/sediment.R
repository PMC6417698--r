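# Sediment track: Hakanson potential ecological risk factors (Eri) and
# index (RI), as deterministic point estimates and as Monte Carlo grade
# probability distributions.

ERI_BREAKS <- c(0, 40, 80, 160, 320, Inf)
ERI_GRADES <- c("low", "moderate", "considerable", "high", "very_high")
RI_BREAKS <- c(0, 150, 300, 600, Inf)
RI_GRADES <- c("low", "moderate", "considerable", "high")

#' Risk grade of a potential ecological risk factor or index
#'
#' Grades are half-open bands with an inclusive lower bound:
#' Eri `[0,40)` low, `[40,80)` moderate, `[80,160)` considerable,
#' `[160,320)` high, `[320,Inf)` very_high; RI `[0,150)` low,
#' `[150,300)` moderate, `[300,600)` considerable, `[600,Inf)` high.
#'
#' @param value Nonnegative Eri (or RI) value(s).
#' @return Character vector of grades.
#' @examples
#' grade_eri(c(39.999, 40))  # "low" "moderate"
#' grade_ri(150)             # "moderate"
#' @export
grade_eri <- function(value) {
  if (any(value < 0)) stop("grade_eri: negative risk factor")
  as.character(cut(value, ERI_BREAKS, labels = ERI_GRADES, right = FALSE))
}

#' @rdname grade_eri
#' @export
grade_ri <- function(value) {
  if (any(value < 0)) stop("grade_ri: negative risk index")
  as.character(cut(value, RI_BREAKS, labels = RI_GRADES, right = FALSE))
}

#' Potential ecological risk factor of one metal
#'
#' `Eri = Tri * C / Cri`: the toxic response factor times the contamination
#' factor (measured sediment concentration over the background reference
#' level). Linear in the concentration.
#'
#' @param concentration Sediment concentration(s), mg/kg dry weight (> 0).
#' @param metal One of [metals()].
#' @param ref A [default_reference()]-style reference table.
#' @return data.frame with columns `metal, concentration, eri, grade`
#'   (one row per concentration).
#' @examples
#' eri(11.49, "As")  # Eri = 5.745, low
#' @export
eri <- function(concentration, metal, ref = default_reference()) {
  metal <- match.arg(metal, metals())
  if (!metal %in% names(ref$tri) || !metal %in% names(ref$cri)) {
    stop("eri: metal '", metal, "' missing from the reference table")
  }
  if (any(concentration <= 0)) stop("eri: concentrations must be > 0")
  e <- ref$tri[[metal]] * concentration / ref$cri[[metal]]
  data.frame(metal = metal, concentration = concentration, eri = e,
             grade = grade_eri(e))
}

#' Composite potential ecological risk index
#'
#' `RI = sum(Eri)` over the assessed metals, graded on the four-band RI
#' scheme. Duplicate metals are an error (each metal contributes once).
#'
#' @param eris A data.frame as returned by (possibly rbind-ed) [eri()]
#'   calls: one row per metal with columns `metal` and `eri`.
#' @return One-row data.frame `ri, grade`.
#' @export
ri <- function(eris) {
  if (anyDuplicated(eris$metal)) {
    stop("ri: duplicate metal(s): ",
         paste(unique(eris$metal[duplicated(eris$metal)]), collapse = ", "))
  }
  total <- sum(eris$eri)
  data.frame(ri = total, grade = grade_ri(total))
}

grade_percentages <- function(values, breaks, labels) {
  counts <- table(cut(values, breaks, labels = labels, right = FALSE))
  pct <- 100 * as.numeric(counts) / length(values)
  stats::setNames(pct, labels)
}

#' Monte Carlo grade probabilities of Eri for one metal
#'
#' Draws `n_draws` concentrations from a fitted exposure distribution,
#' maps them through [eri()] arithmetic and tabulates the percentage of
#' draws falling in each risk grade. This replaces the single-point Eri
#' estimate by a probability statement about the grade.
#'
#' @param dist A [risk_dist()] fitted to this metal's sediment
#'   concentrations (mg/kg dry weight).
#' @param metal One of [metals()].
#' @param ref Reference table.
#' @param n_draws Number of Monte Carlo draws (default 100000).
#' @param seed Optional integer seed; same seed, same result.
#' @return Object of class `risk_distribution`: list with `kind`
#'   (`"eri"`), `metal`, `n_draws`, `samples`, `mean`, and
#'   `grade_probabilities` (percentages over the five Eri grades, summing
#'   to 100).
#' @export
mc_eri <- function(dist, metal, ref = default_reference(),
                   n_draws = 100000, seed = NULL) {
  metal <- match.arg(metal, metals())
  conc <- dist_sample(dist, n_draws, seed)
  e <- ref$tri[[metal]] * conc / ref$cri[[metal]]
  structure(
    list(kind = "eri", metal = metal, n_draws = n_draws, samples = e,
         mean = mean(e),
         grade_probabilities = grade_percentages(e, ERI_BREAKS, ERI_GRADES)),
    class = "risk_distribution"
  )
}

#' Monte Carlo grade probabilities of the composite index RI
#'
#' Samples each metal's concentration independently from its fitted
#' distribution, sums the per-draw risk factors into RI, and tabulates the
#' four RI grades. All seven metals must be supplied.
#'
#' @param dists Named list mapping every metal in [metals()] to a fitted
#'   [risk_dist()].
#' @inheritParams mc_eri
#' @return A `risk_distribution` with `kind = "ri"` and the four RI grade
#'   percentages.
#' @export
mc_ri <- function(dists, ref = default_reference(), n_draws = 100000,
                  seed = NULL) {
  missing <- setdiff(metals(), names(dists))
  if (length(missing) > 0) {
    stop("mc_ri: missing metal(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  total <- numeric(n_draws)
  for (m in metals()) {
    conc <- dist_sample(dists[[m]], n_draws)   # one shared RNG stream
    total <- total + ref$tri[[m]] * conc / ref$cri[[m]]
  }
  structure(
    list(kind = "ri", metal = NA_character_, n_draws = n_draws,
         samples = total, mean = mean(total),
         grade_probabilities = grade_percentages(total, RI_BREAKS, RI_GRADES)),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat("<risk_distribution>", toupper(x$kind),
      if (!is.na(x$metal)) paste0("(", x$metal, ")") else "",
      "- n_draws:", x$n_draws, "\n")
  cat("  mean:", signif(x$mean, 5), "\n")
  cat("  grade probabilities (%):\n")
  print(round(x$grade_probabilities, 4))
  invisible(x)
}
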