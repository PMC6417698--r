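test_that("log-logistic parameters are recovered from simulated data", {
  set.seed(1)
  x <- rllogis(500, alpha = 10, beta = 5)
  f <- fit_mle("log_logistic", x)
  expect_lt(abs(f$params[["alpha"]] - 10) / 10, 0.05)
  expect_lt(abs(f$params[["beta"]] - 5) / 5, 0.15)
  expect_true(f$convergence)
  expect_identical(f$n, 500L)
})

test_that("every family recovers its own parameters (scale 10%, shape 20% median error)", {
  truth <- list(
    log_normal = list(p = c(meanlog = 1.5, sdlog = 0.5),
                      gen = function(n) stats::rlnorm(n, 1.5, 0.5),
                      scale = "meanlog", shape = "sdlog"),
    log_logistic = list(p = c(alpha = 8, beta = 3),
                        gen = function(n) rllogis(n, 8, 3),
                        scale = "alpha", shape = "beta"),
    weibull = list(p = c(scale = 6, shape = 2),
                   gen = function(n) stats::rweibull(n, 2, 6),
                   scale = "scale", shape = "shape"),
    burr3 = list(p = c(b = 5, c = 4, k = 1.5),
                 gen = function(n) rburr3(n, 5, 4, 1.5),
                 scale = "b", shape = "c")
  )
  for (fam in names(truth)) {
    tr <- truth[[fam]]
    err_scale <- err_shape <- numeric(20)
    for (s in 1:20) {
      set.seed(s + 100)
      f <- fit_mle(fam, tr$gen(500))
      err_scale[s] <- abs(f$params[[tr$scale]] - tr$p[[tr$scale]]) /
        abs(tr$p[[tr$scale]])
      err_shape[s] <- abs(f$params[[tr$shape]] - tr$p[[tr$shape]]) /
        abs(tr$p[[tr$shape]])
    }
    expect_lt(stats::median(err_scale), 0.10, label = paste(fam, "scale"))
    expect_lt(stats::median(err_shape), 0.20, label = paste(fam, "shape"))
  }
})

test_that("fitted log-likelihoods match an independent optimizer", {
  skip_if_not_installed("fitdistrplus")
  set.seed(7)
  x <- rllogis(200, 10, 5)
  f <- fit_mle("log_logistic", x)
  ref <- suppressWarnings(fitdistrplus::fitdist(
    x, "llogis", start = list(alpha = stats::median(x), beta = 5),
    control = list(reltol = 1e-12)
  ))
  expect_equal(f$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-7)
  fw <- fit_mle("weibull", x)
  refw <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fw$log_likelihood, as.numeric(stats::logLik(refw)),
               tolerance = 1e-6)
})

test_that("degenerate and invalid data are refused", {
  expect_error(fit_mle("log_logistic", rep(2, 10)), "constant")
  expect_error(fit_mle("weibull", c(1, 2)), "at least 3")
  expect_error(fit_mle("log_normal", c(1, 2, -3)), "> 0")
})

test_that("burr3 on log-logistic data sits near its nested case or is flagged", {
  set.seed(3)
  x <- rllogis(500, 10, 5)
  f <- fit_mle("burr3", x)
  expect_true(f$limit_flag || (f$params[["k"]] > 0.2 && f$params[["k"]] < 5))
})

test_that("AIC follows the formula and pays the extra-parameter penalty", {
  d <- risk_dist("log_logistic", c(alpha = 1, beta = 1),
                 log_likelihood = -100, n = 50L)
  expect_equal(aic(d), 204)
  d3 <- risk_dist("burr3", c(b = 1, c = 1, k = 1),
                  log_likelihood = -100, n = 50L)
  expect_equal(aic(d3), aic(d) + 2)
  expect_error(aic(risk_dist("weibull", c(scale = 1, shape = 1))),
               "no log-likelihood")
})

test_that("AIC ordering is invariant to data permutation", {
  set.seed(9)
  x <- rllogis(150, 5, 2)
  a1 <- vapply(dist_families(), function(f) aic(fit_mle(f, x)), 0)
  a2 <- vapply(dist_families(), function(f) aic(fit_mle(f, sample(x))), 0)
  expect_equal(order(a1), order(a2))
  expect_equal(a1, a2, tolerance = 1e-6)
})
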