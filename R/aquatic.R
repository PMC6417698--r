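# Aquatic risk characterization: hazard quotients, joint probability
# curves and the overall risk probability.

#' Hazard quotient
#'
#' `HQ = EEC / PNEC`. A quotient above 1 flags potential ecological risk;
#' the boundary HQ = 1 is classified acceptable.
#'
#' @param eec Environmental exposure concentration, ug/L (> 0).
#' @param pnec Predicted no-effect concentration, ug/L (> 0).
#' @return One-row data.frame `eec, pnec, hq, flag` with `flag` one of
#'   `"acceptable"` (hq <= 1) or `"potential_risk"`.
#' @examples
#' hazard_quotient(2.58, 0.17)  # HQ about 15.2, potential risk
#' @export
hazard_quotient <- function(eec, pnec) {
  if (any(eec <= 0) || any(pnec <= 0)) {
    stop("hazard_quotient: eec and pnec must be > 0")
  }
  hq <- eec / pnec
  data.frame(eec = eec, pnec = pnec, hq = hq,
             flag = ifelse(hq <= 1, "acceptable", "potential_risk"))
}

as_dist <- function(x) {
  if (inherits(x, "ssd_model")) x$fitted else x
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Joint probability curve and overall risk probability
#'
#' For each proportion `x` of species affected, the curve plots the
#' exceedance probability of the exposure distribution at the
#' concentration affecting that proportion:
#' `EXP(x) = 1 - F_exposure(Q_ssd(x))`. The area under the curve is the
#' overall risk probability `ORP = integral of EXP(x) dx`, equivalently
#' the probability that a random exposure concentration exceeds a random
#' species tolerance. The integral is evaluated by the trapezoid rule on a
#' uniform open grid, with the endpoints extended by the limits
#' `EXP(0+) = 1` and `EXP(1-) = 0`.
#'
#' @param ssd An [ssd_model] or a [risk_dist()] for species tolerances
#'   (ug/L).
#' @param exposure A [risk_dist()] fitted to exposure concentrations
#'   (ug/L).
#' @param grid_size Number of interior grid points (>= 11, default 10001).
#' @return Object of class `jpc_result`: list with `grid` (interior
#'   proportions), `exp_values` (exceedance probabilities, nonincreasing),
#'   `orp` and `decision` (`"acceptable"` iff orp <= 0.05).
#' @export
jpc <- function(ssd, exposure, grid_size = 10001) {
  if (grid_size < 11) stop("jpc: grid_size must be >= 11")
  sdist <- as_dist(ssd)
  xs <- seq_len(grid_size) / (grid_size + 1)
  cx <- dist_quantile(sdist, xs)
  expv <- 1 - dist_cdf(exposure, cx)
  orp <- trapezoid(c(0, xs, 1), c(1, expv, 0))
  structure(
    list(grid = xs, exp_values = expv, orp = orp,
         decision = classify_orp(orp)),
    class = "jpc_result"
  )
}

#' Monte Carlo oracle for the overall risk probability
#'
#' Estimates `E[F_ssd(C)]` for exposure draws `C`, which equals the ORP
#' integral analytically; used to cross-validate the quadrature in
#' [jpc()]. The Monte Carlo standard error is attached as attribute
#' `"se"`.
#'
#' @inheritParams jpc
#' @param n Number of exposure draws (>= 1e4).
#' @param seed Optional integer seed.
#' @return Numeric ORP estimate with attributes `se` and `n`.
#' @export
orp_oracle <- function(ssd, exposure, n = 1e5, seed = NULL) {
  if (n < 1e4) stop("orp_oracle: need n >= 1e4 draws")
  sdist <- as_dist(ssd)
  draws <- dist_sample(exposure, n, seed)
  paf <- dist_cdf(sdist, draws)   # potentially affected fraction per draw
  est <- mean(paf)
  structure(est, se = stats::sd(paf) / sqrt(n), n = n)
}

#' Classify an overall risk probability
#'
#' The adverse-effect probability is deemed acceptable when it is not
#' higher than 0.05 (boundary inclusive).
#'
#' @param orp Overall risk probability in \[0, 1\].
#' @return `"acceptable"` or `"unacceptable"`.
#' @export
classify_orp <- function(orp) {
  if (any(orp < 0 | orp > 1)) stop("classify_orp: orp must lie in [0, 1]")
  ifelse(orp <= 0.05, "acceptable", "unacceptable")
}

#' @export
print.jpc_result <- function(x, ...) {
  cat("<jpc_result> ORP:", signif(x$orp, 4), "-", x$decision, "\n")
  invisible(x)
}

#' Plot a joint probability curve
#'
#' Proportion of species affected (x) against the exceedance probability
#' of exposure (y); the area under the curve is the ORP.
#'
#' @param x A `jpc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.jpc_result <- function(x, ...) {
  graphics::plot(c(0, x$grid, 1) * 100, c(1, x$exp_values, 0) * 100,
                 type = "l",
                 xlab = "Species affected (%)",
                 ylab = "Exceedance probability of exposure (%)", ...)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("ORP = %.3f (%s)", x$orp, x$decision))
  invisible(x)
}
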