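test_that("generated values respect stratum ranges and are seed-reproducible", {
  sc <- laizhou_scenario()
  a <- gen_concentrations(sc, seed = 4)
  b <- gen_concentrations(sc, seed = 4)
  expect_identical(a, b)
  merged <- merge(a, sc$concentrations,
                  by = c("matrix", "season", "metal"))
  expect_true(all(merged$value >= merged$min & merged$value <= merged$max))
})

test_that("the Hg autumn sediment stratum yields 10 in-range station values", {
  conc <- gen_concentrations(laizhou_scenario(), seed = 6,
                             matrix = "sediment",
                             seasons = "autumn_2016_09",
                             metals_subset = "Hg")
  st <- combine_replicates(conc)
  expect_identical(nrow(st), 10L)
  expect_true(all(st$value >= 0.022 & st$value <= 0.035))
})

test_that("the sd -> 0 limit pins every value at the stratum mean", {
  sc <- laizhou_scenario()
  sc$concentrations <- data.frame(matrix = "seawater",
                                  season = "spring_2016_05", metal = "Cu",
                                  min = 1, max = 3, mean = 2, sd = 1e-9)
  sc$replicate_cv <- 1e-9
  conc <- gen_concentrations(sc, seed = 5)
  expect_equal(conc$value, rep(2, nrow(conc)), tolerance = 1e-6)
})

test_that("infeasible truncation is refused", {
  sc <- laizhou_scenario()
  sc$concentrations <- data.frame(matrix = "seawater",
                                  season = "spring_2016_05", metal = "Cu",
                                  min = 10, max = 10.01, mean = 10.005,
                                  sd = 5)
  expect_error(gen_concentrations(sc, seed = 5), "infeasible truncation")
})

test_that("station means track the scenario means (median over 50 seeds within 15%)", {
  sc <- laizhou_scenario()
  rel_err <- sapply(1:50, function(s) {
    conc <- gen_concentrations(sc, seed = s, matrix = "sediment",
                               seasons = "autumn_2016_09",
                               metals_subset = "Hg")
    abs(mean(combine_replicates(conc)$value) - 0.025) / 0.025
  })
  expect_lt(stats::median(rel_err), 0.15)
})

test_that("toxicity generation follows the per-group record counts", {
  tox <- gen_toxicity(laizhou_scenario(), seed = 7)
  expect_identical(nrow(tox), 336L)
  counts <- table(tox$metal)
  expect_identical(as.integer(counts[c("As", "Cd", "Cr", "Cu", "Hg",
                                       "Pb", "Zn")]),
                   c(23L, 51L, 38L, 123L, 20L, 29L, 52L))
  cu <- tox[tox$metal == "Cu", ]
  expect_identical(as.integer(table(cu$functional_group)[
    c("algae", "crustaceans", "fish", "invertebrates", "mollusks",
      "worms")]), c(38L, 27L, 9L, 15L, 25L, 9L))
  # fully screening-compliant by construction
  kept <- suppressMessages(screen_toxicity(tox))
  expect_identical(nrow(kept), nrow(tox))
})

test_that("closed-loop HC5 recovery from generated toxicity data", {
  sc <- laizhou_scenario()
  true_hc5 <- laizhou_hc5()[["Cu"]]
  errs <- sapply(1:8, function(s) {
    tox <- gen_toxicity(sc, seed = s + 20, metals_subset = "Cu")
    agg <- aggregate_by_species(tox)
    m <- fit_ssd(agg$tolerance_ugL, agg$functional_group, metal = "Cu",
                 ad_B = 29, seed = s + 400)
    abs(m$hc5 - true_hc5) / true_hc5
  })
  expect_lt(stats::median(errs), 0.25)
})

test_that("scenarios round-trip through YAML", {
  sc <- laizhou_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$concentrations, sc$concentrations, tolerance = 1e-12)
  expect_equal(back$stations$longitude, sc$stations$longitude,
               tolerance = 1e-12)
  expect_identical(back$n_replicates, sc$n_replicates)
  expect_equal(back$toxicity$counts, sc$toxicity$counts)
  expect_equal(back$toxicity$ssd, sc$toxicity$ssd, tolerance = 1e-12)
})

test_that("the default scenario encodes the survey design", {
  sc <- laizhou_scenario()
  zn <- sc$concentrations[sc$concentrations$matrix == "seawater" &
                            sc$concentrations$season == "spring_2016_05" &
                            sc$concentrations$metal == "Zn", ]
  expect_equal(zn$mean, 40.48)
  expect_equal(zn$sd, 5.35)
  expect_identical(sum(sc$stations$has_sediment), 10L)
  expect_identical(nrow(sc$stations), 20L)
})
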