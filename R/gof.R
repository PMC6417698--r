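# Goodness-of-fit machinery: Kolmogorov-Smirnov, Anderson-Darling and
# AIC-based model selection across the candidate families.

#' Kolmogorov-Smirnov goodness-of-fit test against a fitted distribution
#'
#' Computes `D = sup |F_n(x) - F(x)|` against the fitted cdf. The default
#' p-value is the naive asymptotic one from [stats::ks.test()], which
#' ignores that parameters were estimated from the same data (and is thus
#' anti-conservative); a seeded parametric bootstrap that refits the family
#' on each resample is available as `p_method = "bootstrap"`.
#'
#' @param dist A fitted [risk_dist()].
#' @param x The data the fit is judged on (n >= 3).
#' @param p_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param B Number of bootstrap resamples when `p_method = "bootstrap"`.
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `statistic` (D), `p_value` and `method`.
#' @export
ks_test <- function(dist, x, p_method = c("asymptotic", "bootstrap"),
                    B = 999, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(x) < 3) stop("ks_test: need at least 3 observations")
  ht <- suppressWarnings(stats::ks.test(x, function(q) dist_cdf(dist, q)))
  D <- unname(ht$statistic)
  if (p_method == "asymptotic") {
    return(list(statistic = D, p_value = unname(ht$p.value),
                method = "asymptotic"))
  }
  stat_fun <- function(d, xx) {
    unname(suppressWarnings(stats::ks.test(xx, function(q) dist_cdf(d, q)))$statistic)
  }
  p <- gof_bootstrap_p(dist, length(x), D, stat_fun, B, seed)
  list(statistic = D, p_value = p, method = "parametric bootstrap")
}

# A^2 by the standard sum over probability-transformed order statistics.
ad_statistic <- function(dist, x) {
  n <- length(x)
  u <- dist_cdf(dist, sort(x))           # stable sort keeps ties ordered
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log(u) + log(1 - rev(u)))) / n
}

# Shared parametric-bootstrap p-value: sample from the fitted model, refit
# the same family, recompute the statistic. Resamples whose refit fails are
# dropped (counted) rather than biasing the null distribution.
gof_bootstrap_p <- function(dist, n, observed, stat_fun, B, seed) {
  if (!is.null(seed)) set.seed(seed)
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    xb <- dist_quantile(dist, stats::runif(n))
    fb <- tryCatch(fit_mle(dist$family, xb), error = function(e) NULL)
    if (is.null(fb)) next
    stats_b[b] <- stat_fun(fb, xb)
  }
  ok <- !is.na(stats_b)
  if (sum(ok) < B / 2) {
    warning("gof bootstrap: more than half of the refits failed")
  }
  (1 + sum(stats_b[ok] >= observed)) / (sum(ok) + 1)
}

#' Anderson-Darling goodness-of-fit test against a fitted distribution
#'
#' The A-squared statistic weights the tails more heavily than
#' Kolmogorov-Smirnov, which is why it is the preferred selector for
#' species sensitivity distributions, where the lower tail (HC5) is the
#' quantity of interest. Because the null distribution of A-squared with
#' estimated parameters has no closed form common to all four families,
#' the p-value is obtained by a seeded parametric bootstrap that refits
#' the family on each resample.
#'
#' @inheritParams ks_test
#' @param B Number of bootstrap resamples (default 999).
#' @return List with `statistic` (A-squared), `p_value` and `method`.
#' @export
ad_test <- function(dist, x, B = 999, seed = NULL) {
  if (length(x) < 3) stop("ad_test: need at least 3 observations")
  A2 <- ad_statistic(dist, x)
  p <- gof_bootstrap_p(dist, length(x), A2, ad_statistic, B, seed)
  list(statistic = A2, p_value = p, method = "parametric bootstrap")
}

#' Fit all candidate families and select the best model
#'
#' Fits each requested family by [fit_mle()] and ranks them by one of the
#' two selection rules used in this package: `"ks_p"` (largest
#' Kolmogorov-Smirnov p-value; used for exposure concentration data) or
#' `"ad_p_aic"` (largest Anderson-Darling bootstrap p-value with AIC as the
#' tie-breaker; used for species sensitivity distributions). Burr III fits
#' flagged as boundary/limit cases are excluded from selection and carry a
#' note in the ranking, mirroring the practice of dropping the Burr III
#' when its limit distribution appears.
#'
#' @param x Positive data vector.
#' @param families Subset of [dist_families()] to try.
#' @param criterion `"ks_p"` or `"ad_p_aic"`.
#' @param ad_B Bootstrap resamples for the Anderson-Darling p-value.
#' @param seed Optional integer seed (drives the AD bootstrap).
#' @return List with `best` (a [risk_dist()]), `ranking` (a data.frame with
#'   one row per family: statistics, p-values, AIC, flags) and `failures`
#'   (named list of fit errors, if any).
#' @export
select_model <- function(x, families = dist_families(),
                         criterion = c("ks_p", "ad_p_aic"),
                         ad_B = 199, seed = NULL) {
  criterion <- match.arg(criterion)
  families <- match.arg(families, dist_families(), several.ok = TRUE)
  fits <- list()
  failures <- list()
  for (fam in families) {
    f <- tryCatch(fit_mle(fam, x), error = function(e) e)
    if (inherits(f, "error")) failures[[fam]] <- conditionMessage(f)
    else fits[[fam]] <- f
  }
  if (length(fits) == 0) {
    stop("select_model: all fits failed:\n",
         paste(names(failures), unlist(failures), sep = ": ", collapse = "\n"))
  }

  rows <- lapply(names(fits), function(fam) {
    d <- fits[[fam]]
    ks <- ks_test(d, x)
    ad_p <- NA_real_
    a2 <- ad_statistic(d, x)
    if (criterion == "ad_p_aic" && !d$limit_flag) {
      ad_p <- ad_test(d, x, B = ad_B, seed = seed)$p_value
    }
    data.frame(
      family = fam, n_params = n_params(d),
      ks_D = ks$statistic, ks_p = ks$p_value,
      ad_A2 = a2, ad_p = ad_p, aic = aic(d),
      limit = d$limit_flag,
      note = if (d$limit_flag) "boundary fit excluded from selection" else "",
      stringsAsFactors = FALSE
    )
  })
  ranking <- do.call(rbind, rows)
  ord <- if (criterion == "ks_p") {
    order(ranking$limit, -ranking$ks_p, ranking$aic)
  } else {
    order(ranking$limit, -ifelse(is.na(ranking$ad_p), -Inf, ranking$ad_p),
          ranking$aic)
  }
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  eligible <- ranking$family[!ranking$limit]
  if (length(eligible) == 0) {
    stop("select_model: every candidate fit was flagged as a boundary case")
  }
  list(best = fits[[eligible[1]]], ranking = ranking, failures = failures)
}
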