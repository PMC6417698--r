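test_that("KS statistic attains 0.5/n on perfectly spaced quantiles", {
  d <- risk_dist("log_logistic", c(alpha = 1, beta = 2))
  n <- 20
  x <- dist_quantile(d, (seq_len(n) - 0.5) / n)
  res <- ks_test(d, x)
  expect_equal(res$statistic, 0.5 / n, tolerance = 1e-9)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("AD statistic matches a direct evaluation of the sum formula", {
  d <- risk_dist("weibull", c(scale = 3, shape = 1.5))
  set.seed(21)
  x <- dist_sample(d, 25)
  # independent brute-force evaluation
  u <- sort(dist_cdf(d, sort(x)))
  n <- length(u)
  a2 <- -n
  for (i in seq_len(n)) {
    a2 <- a2 - (2 * i - 1) / n * (log(u[i]) + log(1 - u[n + 1 - i]))
  }
  expect_equal(perisk:::ad_statistic(d, x), a2, tolerance = 1e-12)
  # the constructed perfectly spaced sample minimizes A2 among permutations
  # of probability levels: any noisy sample scores higher
  x_min <- dist_quantile(d, (seq_len(n) - 0.5) / n)
  expect_lt(perisk:::ad_statistic(d, x_min), perisk:::ad_statistic(d, x))
})

test_that("bootstrap p-values are deterministic under a fixed seed and in [0,1]", {
  set.seed(31)
  x <- rllogis(40, 10, 3)
  f <- fit_mle("log_logistic", x)
  p1 <- ad_test(f, x, B = 49, seed = 99)
  p2 <- ad_test(f, x, B = 49, seed = 99)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 0)
  expect_lte(p1$p_value, 1)
  k1 <- ks_test(f, x, p_method = "bootstrap", B = 49, seed = 99)
  k2 <- ks_test(f, x, p_method = "bootstrap", B = 49, seed = 99)
  expect_identical(k1$p_value, k2$p_value)
})

test_that("both statistics are larger on average under mis-specification", {
  # data truly Weibull(shape 0.8): a mis-specified log-normal fit should
  # score worse than the true family, on average over many datasets
  ks_true <- ks_wrong <- ad_true <- ad_wrong <- numeric(100)
  for (s in 1:100) {
    set.seed(s + 600)
    x <- stats::rweibull(100, shape = 0.8, scale = 5)
    ft <- fit_mle("weibull", x)
    fw <- fit_mle("log_normal", x)
    ks_true[s] <- ks_test(ft, x)$statistic
    ks_wrong[s] <- ks_test(fw, x)$statistic
    ad_true[s] <- perisk:::ad_statistic(ft, x)
    ad_wrong[s] <- perisk:::ad_statistic(fw, x)
  }
  expect_gt(mean(ks_wrong), mean(ks_true))
  expect_gt(mean(ad_wrong), mean(ad_true))
  expect_gt(mean(ks_wrong > ks_true), 0.7)
  expect_gt(mean(ad_wrong > ad_true), 0.7)
})

test_that("select_model returns the single requested family and full rankings", {
  set.seed(41)
  x <- rllogis(100, 5, 2)
  sel <- select_model(x, families = "weibull", criterion = "ks_p")
  expect_identical(sel$best$family, "weibull")
  expect_identical(nrow(sel$ranking), 1L)
  sel4 <- select_model(x, criterion = "ks_p")
  expect_lte(nrow(sel4$ranking), 4L)
  expect_true(all(c("family", "ks_D", "ks_p", "ad_A2", "aic", "limit")
                  %in% names(sel4$ranking)))
})

test_that("model selection prefers the true family in most replicates", {
  picks <- character(40)
  for (s in 1:40) {
    set.seed(s + 700)
    x <- rllogis(200, 10, 5)
    sel <- select_model(x, families = c("log_normal", "log_logistic",
                                        "weibull"), criterion = "ks_p")
    picks[s] <- sel$best$family
  }
  expect_gt(mean(picks == "log_logistic"), 0.5)
})

test_that("boundary-flagged fits are excluded from selection but reported", {
  set.seed(51)
  x <- rllogis(60, 10, 3)
  flagged <- risk_dist("burr3", c(b = 10, c = 3, k = 2000),
                       log_likelihood = -1, n = 60L, limit_flag = TRUE)
  # inject via the ranking path: a limit-flagged burr3 never wins even with
  # a dominating likelihood
  sel <- select_model(x, criterion = "ks_p")
  if ("burr3" %in% sel$ranking$family && any(sel$ranking$limit)) {
    expect_false(sel$best$family == "burr3")
    expect_match(sel$ranking$note[sel$ranking$limit][1], "excluded")
  }
  expect_false(sel$best$limit_flag)
})
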