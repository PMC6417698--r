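# Distribution families used for exposure data and species sensitivity
# distributions. All four families live on the positive reals; the
# log-logistic and Burr III are provided here, the log-normal and Weibull
# come from 'stats'.

#' Supported distribution families
#'
#' The closed set of parametric families used for exposure concentration
#' data and species sensitivity distributions: log-normal, log-logistic,
#' Weibull and Burr III (Burr XII of the inverse variable).
#'
#' Parameterizations (all parameters strictly positive):
#' \describe{
#'   \item{log_normal}{`meanlog`, `sdlog` as in [stats::dlnorm()].}
#'   \item{log_logistic}{scale `alpha`, shape `beta`;
#'     `F(x) = 1 / (1 + (x/alpha)^-beta)`. The median equals `alpha`.}
#'   \item{weibull}{scale `scale`, shape `shape` as in [stats::dweibull()].}
#'   \item{burr3}{scale `b`, shapes `c` and `k`;
#'     `F(x) = (1 + (x/b)^-c)^-k`. With `k = 1` this reduces to the
#'     log-logistic with `alpha = b`, `beta = c`.}
#' }
#'
#' @return Character vector of family names.
#' @export
dist_families <- function() {
  c("log_normal", "log_logistic", "weibull", "burr3")
}

# numerically stable log(1 + exp(t))
log1pexp <- function(t) {
  pmax(t, 0) + log1p(exp(-abs(t)))
}

#' The log-logistic distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the log-logistic distribution with scale `alpha` (the median) and
#' shape `beta`. `log(X)` follows a logistic distribution with location
#' `log(alpha)` and scale `1/beta`.
#'
#' @param x,q Vector of quantiles (positive).
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param alpha Scale parameter (> 0); equals the median.
#' @param beta Shape parameter (> 0); larger values mean less spread.
#' @param log,lower.tail As in [stats::dlnorm()].
#' @return `dllogis` the density, `pllogis` the cdf, `qllogis` quantiles,
#'   `rllogis` random draws.
#' @examples
#' pllogis(2, alpha = 2, beta = 5)   # 0.5: the scale is the median
#' qllogis(0.05, alpha = 1, beta = 1) # 1/19
#' @export
dllogis <- function(x, alpha, beta, log = FALSE) {
  if (any(alpha <= 0) || any(beta <= 0)) return(rep(NaN, length(x)))
  ld <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- beta * (base::log(x[ok]) - base::log(alpha))
  ld[ok] <- base::log(beta) - base::log(x[ok]) + t - 2 * log1pexp(t)
  if (log) ld else exp(ld)
}

#' @rdname dllogis
#' @export
pllogis <- function(q, alpha, beta, lower.tail = TRUE) {
  if (any(alpha <= 0) || any(beta <= 0)) return(rep(NaN, length(q)))
  p <- numeric(length(q))
  pos <- q > 0
  p[pos] <- stats::plogis(beta * (base::log(q[pos]) - base::log(alpha)))
  if (lower.tail) p else 1 - p
}

#' @rdname dllogis
#' @export
qllogis <- function(p, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) return(rep(NaN, length(p)))
  if (any(p <= 0 | p >= 1)) stop("qllogis: p must lie strictly in (0, 1)")
  alpha * exp(stats::qlogis(p) / beta)
}

#' @rdname dllogis
#' @export
rllogis <- function(n, alpha, beta) {
  alpha * exp(stats::rlogis(n) / beta)
}

#' The Burr III distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Burr III distribution with scale `b` and shape parameters `c`
#' and `k`: `F(x) = (1 + (x/b)^-c)^-k`. Setting `k = 1` recovers the
#' log-logistic distribution with `alpha = b`, `beta = c`.
#'
#' @inheritParams dllogis
#' @param b Scale parameter (> 0).
#' @param c Shape parameter (> 0).
#' @param k Shape parameter (> 0); `k = 1` is the log-logistic special case.
#' @return `dburr3` the density, `pburr3` the cdf, `qburr3` quantiles,
#'   `rburr3` random draws.
#' @examples
#' pburr3(2, b = 2, c = 3, k = 1.5)  # 2^-1.5 at the scale
#' @export
dburr3 <- function(x, b, c, k, log = FALSE) {
  if (any(b <= 0) || any(c <= 0) || any(k <= 0)) return(rep(NaN, length(x)))
  ld <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  t <- -c * (base::log(x[ok]) - base::log(b))  # log((x/b)^-c)
  ld[ok] <- base::log(k) + base::log(c) - base::log(x[ok]) + t -
    (k + 1) * log1pexp(t)
  if (log) ld else exp(ld)
}

#' @rdname dburr3
#' @export
pburr3 <- function(q, b, c, k, lower.tail = TRUE) {
  if (any(b <= 0) || any(c <= 0) || any(k <= 0)) return(rep(NaN, length(q)))
  p <- numeric(length(q))
  pos <- q > 0
  t <- -c * (base::log(q[pos]) - base::log(b))
  p[pos] <- exp(-k * log1pexp(t))
  if (lower.tail) p else 1 - p
}

#' @rdname dburr3
#' @export
qburr3 <- function(p, b, c, k) {
  if (any(b <= 0) || any(c <= 0) || any(k <= 0)) return(rep(NaN, length(p)))
  if (any(p <= 0 | p >= 1)) stop("qburr3: p must lie strictly in (0, 1)")
  # (p^(-1/k) - 1)^(-1/c), written via expm1 for small exponents
  b * expm1(-base::log(p) / k)^(-1 / c)
}

#' @rdname dburr3
#' @export
rburr3 <- function(n, b, c, k) {
  qburr3(stats::runif(n), b, c, k)
}

#' Construct a fitted/parametric distribution object
#'
#' A light container for a parametric distribution on the positive reals,
#' as produced by [fit_mle()] or built directly from known parameters.
#'
#' @param family One of [dist_families()], or `"point_mass"` for the
#'   degenerate single-value distribution (useful to collapse Monte Carlo
#'   stages onto their deterministic counterparts).
#' @param params Named numeric vector of parameters: `log_normal`
#'   `(meanlog, sdlog)`; `log_logistic` `(alpha, beta)`; `weibull`
#'   `(scale, shape)`; `burr3` `(b, c, k)`; `point_mass` `(value)`.
#' @param log_likelihood Log-likelihood at the parameters (NA if not fitted).
#' @param n Number of observations the fit used (NA if not fitted).
#' @param convergence Logical, did the optimizer report convergence.
#' @param limit_flag Logical, set by [fit_mle()] when a Burr III fit ran to
#'   a boundary of its shape `k` (the "limit distribution" case), where the
#'   family degenerates and its fit should not be trusted.
#' @return An object of class `risk_dist`.
#' @export
risk_dist <- function(family, params, log_likelihood = NA_real_,
                      n = NA_integer_, convergence = TRUE,
                      limit_flag = FALSE) {
  family <- match.arg(family, c(dist_families(), "point_mass"))
  expected <- switch(family,
    log_normal   = c("meanlog", "sdlog"),
    log_logistic = c("alpha", "beta"),
    weibull      = c("scale", "shape"),
    burr3        = c("b", "c", "k"),
    point_mass   = "value"
  )
  if (is.null(names(params))) names(params) <- expected
  if (!setequal(names(params), expected)) {
    stop("risk_dist: '", family, "' needs parameters (",
         paste(expected, collapse = ", "), ")")
  }
  params <- params[expected]
  scale_like <- setdiff(expected, "meanlog")
  if (any(params[scale_like] <= 0)) {
    stop("risk_dist: scale/shape parameters must be strictly positive")
  }
  structure(
    list(family = family, params = params,
         log_likelihood = log_likelihood, n = n,
         convergence = convergence, limit_flag = limit_flag),
    class = "risk_dist"
  )
}

#' @rdname risk_dist
#' @param value The single support point of a degenerate distribution.
#' @export
dist_point_mass <- function(value) {
  stopifnot(value > 0)
  risk_dist("point_mass", c(value = value))
}

#' @export
print.risk_dist <- function(x, ...) {
  cat("<risk_dist> family:", x$family, "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 5),
                         sep = " = ", collapse = ", "), "\n")
  if (!is.na(x$log_likelihood)) {
    cat("  logLik:", format(x$log_likelihood), " n:", x$n, "\n")
  }
  if (isTRUE(x$limit_flag)) cat("  [flagged: boundary/limit fit]\n")
  invisible(x)
}

n_params <- function(dist) {
  switch(dist$family, burr3 = 3L, point_mass = 1L, 2L)
}

#' Evaluate a fitted distribution
#'
#' Density, cdf, quantile function and seeded inverse-transform sampling for
#' a [risk_dist()] object, dispatching on its family.
#'
#' @param dist A `risk_dist` object.
#' @param x,q Positive quantiles.
#' @param p Probabilities strictly in (0, 1) for `dist_quantile`.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; the same seed yields identical draws.
#' @return Numeric vector.
#' @export
dist_cdf <- function(dist, q) {
  if (any(q <= 0)) stop("dist_cdf: quantiles must be positive")
  pr <- dist$params
  switch(dist$family,
    log_normal   = stats::plnorm(q, pr[["meanlog"]], pr[["sdlog"]]),
    log_logistic = pllogis(q, pr[["alpha"]], pr[["beta"]]),
    weibull      = stats::pweibull(q, pr[["shape"]], pr[["scale"]]),
    burr3        = pburr3(q, pr[["b"]], pr[["c"]], pr[["k"]]),
    point_mass   = as.numeric(q >= pr[["value"]])
  )
}

#' @rdname dist_cdf
#' @export
dist_density <- function(dist, x) {
  pr <- dist$params
  switch(dist$family,
    log_normal   = stats::dlnorm(x, pr[["meanlog"]], pr[["sdlog"]]),
    log_logistic = dllogis(x, pr[["alpha"]], pr[["beta"]]),
    weibull      = stats::dweibull(x, pr[["shape"]], pr[["scale"]]),
    burr3        = dburr3(x, pr[["b"]], pr[["c"]], pr[["k"]]),
    point_mass   = stop("dist_density: point mass has no density")
  )
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(dist, p) {
  if (any(p <= 0 | p >= 1)) {
    stop("dist_quantile: p must lie strictly in (0, 1)")
  }
  pr <- dist$params
  switch(dist$family,
    log_normal   = stats::qlnorm(p, pr[["meanlog"]], pr[["sdlog"]]),
    log_logistic = qllogis(p, pr[["alpha"]], pr[["beta"]]),
    weibull      = stats::qweibull(p, pr[["shape"]], pr[["scale"]]),
    burr3        = qburr3(p, pr[["b"]], pr[["c"]], pr[["k"]]),
    point_mass   = rep(pr[["value"]], length(p))
  )
}

#' @rdname dist_cdf
#' @export
dist_sample <- function(dist, n, seed = NULL) {
  if (n < 1) stop("dist_sample: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (dist$family == "point_mass") {
    return(rep(dist$params[["value"]], n))
  }
  dist_quantile(dist, stats::runif(n))
}
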