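pct_of <- function(dt, m) {
  dt$percent[dt$measure == m][order(match(
    dt$catchment_level[dt$measure == m],
    c("neighborhood", "subdistrict", "district", "zero")
  ))]
}

test_that("the published national distribution table reproduces exactly", {
  dt <- distribution_table(table1_districts(), weight = "n_districts",
                           totals = table1_totals())
  expect_equal(pct_of(dt, "insured_total"), c(69.33, 20.25, 9.26, 1.07))
  expect_equal(pct_of(dt, "population_total"), c(51.42, 27.77, 18.40, 2.41))
  expect_equal(pct_of(dt, "insured_poor"), c(46.77, 31.67, 19.18, 2.37))
  expect_equal(pct_of(dt, "insured_rich"), c(70.23, 24.21, 5.15, 0.41))
  expect_equal(pct_of(dt, "districts"), c(23.81, 37.04, 32.80, 6.35))
  expect_equal(pct_of(dt, "hccs"), c(78.07, 16.53, 5.41, 0.00))
})

test_that("distribution counts conserve input totals and percentages sum to ~100", {
  sim <- simulate_country(scenario_config(seed = 5, n_states = 4,
                                          districts_per_state = 8))
  d <- classify_districts(sim$districts)
  dt <- distribution_table(d)

  sums <- tapply(dt$count, dt$measure, sum)
  expect_equal(unname(sums[["population_total"]]), sum(d$population_total))
  expect_equal(unname(sums[["insured_total"]]), sum(d$insured_total))
  expect_equal(unname(sums[["insured_poor"]]), sum(d$insured_poor))
  expect_equal(unname(sums[["insured_rich"]]), sum(d$insured_rich))
  expect_equal(unname(sums[["districts"]]), nrow(d))
  expect_equal(unname(sums[["hccs"]]), sum(d$n_hcc))

  psums <- tapply(dt$percent, dt$measure, sum)
  expect_true(all(abs(psums - 100) <= 0.05))

  single <- distribution_table(classify_districts(make_district()))
  expect_true(all(single$percent[single$count > 0] == 100))
  expect_error(distribution_table(d[0, ]), "empty")
})

test_that("district utilization rates divide visits by accessible insured, guarding zero", {
  d <- dplyr::bind_rows(
    make_district(district_id = "a", visits_total = 137, insured_total = 100,
                  insured_poor = 40, insured_rich = 60, visits_poor = 60,
                  visits_rich = 77),
    make_district(district_id = "b", visits_total = 0, visits_poor = 0,
                  visits_rich = 0),
    make_district(district_id = "c", insured_total = 0, insured_poor = 0,
                  insured_rich = 0, visits_total = 0, visits_poor = 0,
                  visits_rich = 0)
  )
  r <- district_utilization_rate(d)$utilization_rate
  expect_equal(r[1], 1.37)
  expect_equal(r[2], 0)
  expect_true(is.na(r[3]))
})

test_that("scope-level rates pool visits over the N, MTN and full groups", {
  d <- dplyr::bind_rows(
    make_district(district_id = "n1", hcc = c(2L, 1L), visits_total = 150,
                  insured_total = 100, insured_poor = 50, insured_rich = 50,
                  visits_poor = 90, visits_rich = 60),
    make_district(district_id = "m1", hcc = c(1L, 0L), visits_total = 30,
                  insured_total = 100, insured_poor = 50, insured_rich = 50,
                  visits_poor = 10, visits_rich = 20)
  )
  r <- utilization_rates(classify_districts(d))
  nat <- r[r$scope == "national", ]
  expect_equal(nat$n_rate, 1.5)
  expect_equal(nat$mtn_rate, 0.3)
  expect_equal(nat$geographic_rate, 0.9)
  expect_equal(nat$poor_n_rate, 1.8)
  expect_equal(nat$rich_mtn_rate, 0.4)

  # degenerate: every district N -> MTN rate undefined, geographic = N rate
  all_n <- classify_districts(d[1, ])
  rn <- utilization_rates(all_n)[1, ]
  expect_true(is.na(rn$mtn_rate))
  expect_equal(rn$geographic_rate, rn$n_rate)
})

test_that("rates are invariant to proportionally splitting a district", {
  sim <- simulate_country(scenario_config(seed = 3, n_states = 3,
                                          districts_per_state = 6))
  d <- classify_districts(sim$districts)
  before <- utilization_rates(d)

  split_me <- d[7, ]
  halves <- dplyr::bind_rows(split_me, split_me)
  num <- c("population_total", "insured_total", "insured_poor",
           "insured_rich", "visits_total", "visits_poor", "visits_rich",
           "cost_local")
  halves[num] <- halves[num] / 2
  halves$district_id <- paste0(split_me$district_id, c("a", "b"))
  after <- utilization_rates(dplyr::bind_rows(d[-7, ], halves))

  expect_equal(
    dplyr::select(after, -"n_districts"),
    dplyr::select(before, -"n_districts")
  )
})

test_that("geographic rate lies between the N and MTN rates when both defined", {
  sim <- simulate_country(paper_regime(seed = 4))
  r <- utilization_rates(classify_districts(sim$districts))
  both <- !is.na(r$n_rate) & !is.na(r$mtn_rate)
  expect_true(any(both))
  expect_true(all(
    r$geographic_rate[both] >= pmin(r$n_rate, r$mtn_rate)[both] &
      r$geographic_rate[both] <= pmax(r$n_rate, r$mtn_rate)[both]
  ))
})

test_that("per-capita cost converts at the buying rate and scales with it", {
  d <- classify_districts(make_district(hcc = c(1L, 1L), cost_local = 700,
                                        insured_total = 50, insured_poor = 20,
                                        insured_rich = 30, visits_total = 60,
                                        visits_poor = 25, visits_rich = 35))
  cc <- cost_per_capita(d, fx_rate = 7)
  expect_equal(cc$cost_usd_per_capita[cc$catchment_level == "subdistrict"], 2)

  sim <- classify_districts(simulate_country(
    scenario_config(seed = 8, n_states = 2, districts_per_state = 6)
  )$districts)
  expect_equal(cost_per_capita(sim, fx_rate = 7)$cost_usd_per_capita,
               cost_per_capita(sim, fx_rate = 1)$cost_usd_per_capita / 7)
  expect_equal(cost_per_capita(sim, fx_rate = 3.5)$cost_usd_per_capita,
               cost_per_capita(sim, fx_rate = 7)$cost_usd_per_capita * 2)

  # zero-cost category with insured present is a true 0, not undefined
  z <- classify_districts(make_district(hcc = c(0L, 0L), cost_local = 0,
                                        visits_total = 0, visits_poor = 0,
                                        visits_rich = 0))
  cz <- cost_per_capita(z)
  expect_equal(cz$cost_usd_per_capita[cz$catchment_level == "zero"], 0)
})

test_that("density classes bin the insured share at 20/40/60/80", {
  expect_equal(
    as.character(density_class(c(19, 20, 39.9, 40, 59, 60, 79, 80, 100), 100)),
    c("very_low", "low", "low", "moderate", "moderate", "high", "high",
      "very_high", "very_high")
  )
  expect_error(density_class(10, 0), "positive")

  d <- dplyr::bind_rows(
    make_district(district_id = "a", insured_total = 10, insured_poor = 4,
                  insured_rich = 6, visits_total = 12, visits_poor = 5,
                  visits_rich = 7),
    make_district(district_id = "b", insured_total = 90, insured_poor = 40,
                  insured_rich = 50, visits_total = 95, visits_poor = 45,
                  visits_rich = 50, population_total = 2000)
  )
  dc <- add_density_class(d)
  expect_equal(as.character(dc$density_class), c("very_low", "very_high"))
  expect_equal(dc$density_pct, c(10, 90))
})
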