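test_that("the same seed reproduces a byte-identical districts CSV", {
  cfg <- scenario_config(seed = 17, n_states = 3, districts_per_state = 5)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_districts(simulate_country(cfg)$districts, f1)
  write_districts(simulate_country(cfg)$districts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("different seeds change the draws but not the condition hash", {
  a <- paper_regime(seed = 1)
  b <- paper_regime(seed = 2)
  expect_identical(scenario_hash(a), scenario_hash(b))
  expect_false(identical(simulate_country(a)$districts$insured_total,
                         simulate_country(b)$districts$insured_total))
  expect_false(scenario_hash(a) ==
                 scenario_hash(paper_regime(seed = 1, fx_rate = 8)))
})

test_that("scenario configurations round-trip through YAML", {
  cfg <- paper_regime(seed = 9, hcc_budget = 1500)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(cfg, f)
  expect_equal(read_scenario(f), cfg)
})

test_that("invalid scenario parameters are rejected", {
  expect_error(scenario_config(insurance_coverage = 0), "insurance_coverage")
  expect_error(scenario_config(visit_prob = c(neighborhood = 1, subdistrict = 1,
                                              district = 1, zero = 0.1)),
               "zero")
  expect_error(scenario_config(hcc_budget = 0), "positive")
  expect_error(
    simulate_country(scenario_config(seed = 1, n_states = 2,
                                     districts_per_state = 2,
                                     allocation_policy = "equitable",
                                     hcc_budget = 3)),
    "infeasible"
  )
})

test_that("the poor/rich split partitions the insured exactly", {
  for (policy in c("density_proportional", "equitable", "per_capita_target")) {
    sim <- simulate_country(scenario_config(seed = 6, n_states = 4,
                                            districts_per_state = 10,
                                            allocation_policy = policy))
    d <- sim$districts
    expect_equal(d$insured_poor + d$insured_rich, as.numeric(d$insured_total))
  }
})

test_that("the classifier recovers the generator's intended category", {
  for (policy in c("density_proportional", "equitable", "per_capita_target")) {
    sim <- simulate_country(scenario_config(seed = 13, n_states = 6,
                                            districts_per_state = 10,
                                            allocation_policy = policy))
    got <- classify_districts(sim$districts)$catchment_level
    want <- sim$ground_truth$districts$intended_category
    expect_gte(mean(got == want), 0.99)
  }
})

test_that("the equitable policy leaves no district below subdistrict coverage", {
  sim <- simulate_country(scenario_config(seed = 23, n_states = 5,
                                          districts_per_state = 8,
                                          allocation_policy = "equitable"))
  lev <- classify_districts(sim$districts)$catchment_level
  expect_true(all(lev %in% c("subdistrict", "neighborhood")))
})

test_that("zero-coverage districts have no facilities, visits or cost", {
  sim <- simulate_country(paper_regime(seed = 1))
  d <- classify_districts(sim$districts)
  z <- d[d$catchment_level == "zero", ]
  expect_gt(nrow(z), 0)
  expect_true(all(z$n_hcc == 0))
  expect_true(all(z$visits_total == 0))
  expect_true(all(z$cost_local == 0))
})

test_that("realized visit volumes recover the configured intensities", {
  cfg <- scenario_config(
    seed = 29,
    visit_prob = c(neighborhood = 0.9, subdistrict = 0.5, district = 0.3,
                   zero = 0),
    poor_visit_multiplier = c(N = 1, MTN = 1)
  )
  sim <- simulate_country(cfg)
  d <- classify_districts(sim$districts)
  for (lev in c("neighborhood", "subdistrict", "district")) {
    sel <- d$catchment_level == lev
    visits <- sum(d$visits_total[sel])
    mu <- cfg$visit_prob[[lev]] * sum(d$insured_total[sel])
    expect_lt(abs(visits - mu), 3 * sqrt(mu)) # 3 Poisson SEs
    # equivalently on the rate scale against the configured probability
    expect_lt(abs(visits / sum(d$insured_total[sel]) - cfg$visit_prob[[lev]]),
              3 * sqrt(mu) / sum(d$insured_total[sel]))
  }
})

test_that("income reporting is masked per state without touching totals", {
  sim <- simulate_country(paper_regime(seed = 2))
  d <- sim$districts
  masked <- !d$income_data_present
  expect_identical(sum(masked) %% sim$ground_truth$config$districts_per_state,
                   0L)
  expect_equal(length(unique(d$state_id[masked])), 5)
  expect_true(all(is.na(d$visits_poor[masked])))
  expect_true(all(!is.na(d$visits_total)))
})

test_that("the reference regime steers facility concentration into dense N districts", {
  d <- classify_districts(simulate_country(paper_regime(seed = 1))$districts)
  n_sel <- d$catchment_level == "neighborhood"
  hcc_share <- sum(d$n_hcc[n_sel]) / sum(d$n_hcc)
  expect_gte(hcc_share, 0.7)
  expect_lte(hcc_share, 0.9)
  expect_gte(sum(d$insured_total[n_sel]) / sum(d$insured_total), 0.6)
  # the poor share of the insured rises as the catchment coarsens
  poor_share <- tapply(d$insured_poor, d$catchment_level, sum) /
    tapply(d$insured_total, d$catchment_level, sum)
  expect_true(all(diff(poor_share[c("neighborhood", "subdistrict",
                                    "district", "zero")]) > 0))
})
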