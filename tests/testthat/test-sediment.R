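test_that("the risk factor is Tri times the contamination factor", {
  ref <- default_reference()
  # concentration at the background level gives Eri = Tri exactly
  for (m in metals()) {
    expect_equal(eri(ref$cri[[m]], m, ref)$eri, ref$tri[[m]])
  }
  # published point estimates for the bay survey means (2 dp precision)
  expect_lt(abs(eri(11.49, "As")$eri - 5.75), 0.005 + 1e-9)
  expect_lt(abs(eri(34.30, "Cr")$eri - 0.86), 0.005 + 1e-9)
  expect_lt(abs(eri(21.75, "Cu")$eri - 3.11), 0.005 + 1e-9)
  expect_error(eri(-1, "As"), "> 0")
})

test_that("eri is linear in concentration", {
  set.seed(2)
  for (m in c("Hg", "Zn")) {
    c0 <- stats::runif(5, 0.01, 10)
    expect_equal(eri(2 * c0, m)$eri, 2 * eri(c0, m)$eri)
  }
})

test_that("grade bands are half-open with inclusive lower bounds", {
  expect_identical(grade_eri(c(39.999, 40)), c("low", "moderate"))
  expect_identical(grade_eri(c(80, 160, 320)),
                   c("considerable", "high", "very_high"))
  expect_identical(grade_ri(c(149.9, 150, 300, 600)),
                   c("low", "moderate", "considerable", "high"))
  expect_error(grade_eri(-0.1), "negative")
})

test_that("RI sums one risk factor per metal and rejects duplicates", {
  eris <- do.call(rbind, lapply(metals(), function(m) eri(1e-6, m)))
  expect_lt(ri(eris)$ri, 1e-3)
  expect_identical(ri(eris)$grade, "low")
  expect_error(ri(rbind(eri(1, "As"), eri(2, "As"))), "duplicate")
})

test_that("Monte Carlo grade probabilities partition 100% and collapse on point masses", {
  d <- risk_dist("log_logistic", c(alpha = 10, beta = 6))
  mc <- mc_eri(d, "As", n_draws = 20000, seed = 5)
  expect_equal(sum(mc$grade_probabilities), 100, tolerance = 1e-9)
  expect_true(all(mc$grade_probabilities >= 0))
  # support entirely below the moderate threshold: 100% low
  tight <- risk_dist("log_normal", c(meanlog = log(10), sdlog = 0.05))
  mc_low <- mc_eri(tight, "As", n_draws = 5000, seed = 6)
  expect_equal(unname(mc_low$grade_probabilities[["low"]]), 100)
  # point mass reproduces the deterministic factor and a single 100% grade
  pm <- mc_eri(dist_point_mass(11.49), "As", n_draws = 1000, seed = 7)
  expect_equal(pm$mean, eri(11.49, "As")$eri)
  expect_equal(unname(pm$grade_probabilities[["low"]]), 100)
})

test_that("Monte Carlo runs are reproducible under a seed", {
  d <- risk_dist("weibull", c(scale = 10, shape = 3))
  a <- mc_eri(d, "Cu", n_draws = 5000, seed = 9)
  b <- mc_eri(d, "Cu", n_draws = 5000, seed = 9)
  expect_identical(a$samples, b$samples)
})

test_that("the RI Monte Carlo matches linearity of expectation and degenerates correctly", {
  set.seed(10)
  dists <- stats::setNames(lapply(metals(), function(m) {
    risk_dist("log_normal", c(meanlog = stats::runif(1, -2, 3), sdlog = 0.4))
  }), metals())
  mc <- mc_ri(dists, n_draws = 50000, seed = 11)
  ref <- default_reference()
  # E[RI] = sum over metals of Tri * E[C] / Cri (independent sampling)
  mu <- sum(vapply(metals(), function(m) {
    p <- dists[[m]]$params
    ref$tri[[m]] * exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2) / ref$cri[[m]]
  }, 0))
  se <- stats::sd(mc$samples) / sqrt(mc$n_draws)
  expect_lt(abs(mc$mean - mu), 4 * se + 0.01 * mu)
  expect_equal(sum(mc$grade_probabilities), 100, tolerance = 1e-9)

  # all point masses: RI Monte Carlo equals the deterministic index
  pm <- stats::setNames(lapply(metals(), function(m) dist_point_mass(1)), metals())
  det <- ri(do.call(rbind, lapply(metals(), function(m) eri(1, m, ref))))
  mcp <- mc_ri(pm, ref, n_draws = 100, seed = 12)
  expect_equal(unique(mcp$samples), det$ri)

  expect_error(mc_ri(dists[1:6], n_draws = 100), "missing metal")
})
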