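#' Scenario configuration for the synthetic-country generator
#'
#' Bundles every parameter of the synthetic country: the administrative
#' hierarchy sizes, the (right-skewed) district population distribution,
#' insurance coverage, the income gradient (poor share rising as density
#' falls), the facility allocation policy, per-category visit intensities,
#' income utilization multipliers, and the cost model. The seed fully
#' determines the generated country.
#'
#' @param seed Integer seed; fully determines the output of
#'   [simulate_country()].
#' @param n_states Number of states.
#' @param districts_per_state Districts in each state (a single count).
#' @param subdistricts_per_district,neighborhoods_per_subdistrict Inclusive
#'   integer ranges `c(lo, hi)` sampled per district / per subdistrict.
#' @param population_meanlog,population_sdlog Lognormal parameters of the
#'   district population: a large `sdlog` gives the strongly right-skewed
#'   density profile in which a few dense districts hold most of the insured.
#' @param insurance_coverage Fraction of the population insured (default
#'   0.438, a realistic national scheme coverage level).
#' @param poor_share_base,poor_share_density_slope The poor fraction of the
#'   insured is `base + slope * (1 - density_percentile)`, clamped to
#'   `[0.05, 0.95]`: poorer districts are the less dense ones.
#' @param allocation_policy How the national HCC budget is distributed:
#'   `"density_proportional"` (budget share proportional to
#'   `insured^allocation_exponent`, snapped to an administrative coverage
#'   tier, so sparse districts may get 0), `"equitable"` (every subdistrict
#'   staffed before any surplus), or `"per_capita_target"` (one HCC per
#'   `insured_per_hcc_target` insured, subdistrict-first).
#' @param allocation_exponent Concentration exponent for
#'   `density_proportional` (1 = exactly proportional; larger concentrates
#'   facilities further into dense districts).
#' @param hcc_budget Total HCCs to allocate; default
#'   `round(total insured / insured_per_hcc_target)`.
#' @param insured_per_hcc_target Health-map planning norm: insured persons
#'   per HCC (default 10,000).
#' @param visit_prob Named vector: expected visits per insured per year by
#'   catchment category; the `zero` entry must be 0 (no facility, no visits).
#' @param poor_visit_multiplier Named vector (`N`, `MTN`): multiplies the
#'   poor stratum's visit intensity relative to the rich stratum.
#' @param income_missing_states Number of states whose income-stratified
#'   visit counts are masked as missing (emulating incomplete income
#'   reporting).
#' @param cost_fixed_per_hcc,cost_per_visit Annual cost components in local
#'   currency.
#' @param remoteness_cost_elasticity Costs scale by
#'   `(median insured / district insured)^elasticity`: unit costs rise as
#'   density falls (remote delivery) and fall with scale in dense districts.
#' @param fx_rate Local currency per USD (default 7).
#' @return A `scenario_config` object (a validated named list).
#' @seealso [paper_regime()], [simulate_country()]
#' @export
scenario_config <- function(seed = 1L,
                            n_states = 18L,
                            districts_per_state = 11L,
                            subdistricts_per_district = c(3L, 8L),
                            neighborhoods_per_subdistrict = c(4L, 12L),
                            population_meanlog = 11.2,
                            population_sdlog = 1.4,
                            insurance_coverage = 0.438,
                            poor_share_base = 0.40,
                            poor_share_density_slope = 0.45,
                            allocation_policy = c("density_proportional",
                                                  "equitable",
                                                  "per_capita_target"),
                            allocation_exponent = 1,
                            hcc_budget = NULL,
                            insured_per_hcc_target = 10000,
                            visit_prob = c(neighborhood = 1.4,
                                           subdistrict = 0.6,
                                           district = 0.25,
                                           zero = 0),
                            poor_visit_multiplier = c(N = 1.2, MTN = 0.6),
                            income_missing_states = 0L,
                            cost_fixed_per_hcc = 1e6,
                            cost_per_visit = 100,
                            remoteness_cost_elasticity = 0.8,
                            fx_rate = 7) {
  allocation_policy <- arg_match(allocation_policy)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_states >= 1, districts_per_state >= 1,
    length(subdistricts_per_district) == 2,
    subdistricts_per_district[1] >= 1,
    diff(subdistricts_per_district) >= 0,
    length(neighborhoods_per_subdistrict) == 2,
    neighborhoods_per_subdistrict[1] >= 1,
    diff(neighborhoods_per_subdistrict) >= 0,
    population_sdlog >= 0,
    insurance_coverage > 0, insurance_coverage <= 1,
    insured_per_hcc_target > 0,
    all(visit_prob >= 0),
    all(poor_visit_multiplier >= 0),
    income_missing_states >= 0, income_missing_states <= n_states,
    cost_fixed_per_hcc >= 0, cost_per_visit >= 0,
    remoteness_cost_elasticity >= 0,
    fx_rate > 0
  )
  if (!setequal(names(visit_prob), catchment_levels())) {
    abort("`visit_prob` must be named by the four catchment levels")
  }
  if (visit_prob[["zero"]] != 0) {
    abort("`visit_prob[\"zero\"]` must be 0: no facility, no visits")
  }
  if (!setequal(names(poor_visit_multiplier), c("N", "MTN"))) {
    abort("`poor_visit_multiplier` must be named N and MTN")
  }
  if (!is.null(hcc_budget) && hcc_budget <= 0) {
    abort("`hcc_budget` must be positive when given")
  }

  structure(
    list(
      seed = as.integer(seed),
      n_states = as.integer(n_states),
      districts_per_state = as.integer(districts_per_state),
      subdistricts_per_district = as.integer(subdistricts_per_district),
      neighborhoods_per_subdistrict = as.integer(neighborhoods_per_subdistrict),
      population_meanlog = population_meanlog,
      population_sdlog = population_sdlog,
      insurance_coverage = insurance_coverage,
      poor_share_base = poor_share_base,
      poor_share_density_slope = poor_share_density_slope,
      allocation_policy = allocation_policy,
      allocation_exponent = allocation_exponent,
      hcc_budget = hcc_budget,
      insured_per_hcc_target = insured_per_hcc_target,
      visit_prob = visit_prob[catchment_levels()],
      poor_visit_multiplier = poor_visit_multiplier[c("N", "MTN")],
      income_missing_states = as.integer(income_missing_states),
      cost_fixed_per_hcc = cost_fixed_per_hcc,
      cost_per_visit = cost_per_visit,
      remoteness_cost_elasticity = remoteness_cost_elasticity,
      fx_rate = fx_rate
    ),
    class = "scenario_config"
  )
}

#' Reference scenario: a density-stratified country
#'
#' A preset of [scenario_config()] emulating the regime in which health-map
#' planning has followed insured density: facilities concentrate into the
#' dense fifth of districts (which end up with neighbourhood-level coverage
#' and hold roughly 70% of the insured and 70-90% of all HCCs), utilization
#' intensity decays as the catchment coarsens, the poor share of the insured
#' rises as density falls, the poor utilize relatively more than the rich
#' where access is at neighbourhood level and relatively less elsewhere, and
#' per-capita cost rises from fine to coarse catchments. Five states do not
#' report income-stratified visits.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
paper_regime <- function(seed = 1L, ...) {
  scenario_config(
    seed = seed,
    allocation_exponent = 1.3,
    income_missing_states = 5L,
    remoteness_cost_elasticity = 1.3,
    ...
  )
}

#' Configuration hash
#'
#' Hash of every scenario parameter except the seed: two scenarios with the
#' same hash describe the same experimental condition run under different
#' random draws.
#'
#' @param cfg A `scenario_config`.
#' @return A character scalar.
#' @export
scenario_hash <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  fields <- cfg[setdiff(sort(names(cfg)), "seed")]
  rlang::hash(fields)
}

#' Read / write scenario configurations as YAML
#'
#' @param cfg A `scenario_config`.
#' @param path A YAML file path.
#' @return `read_scenario()` returns a validated `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- unclass(cfg)
  out$visit_prob <- as.list(out$visit_prob)
  out$poor_visit_multiplier <- as.list(out$poor_visit_multiplier)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$visit_prob <- unlist(raw$visit_prob)
  raw$poor_visit_multiplier <- unlist(raw$poor_visit_multiplier)
  raw$subdistricts_per_district <- unlist(raw$subdistricts_per_district)
  raw$neighborhoods_per_subdistrict <- unlist(raw$neighborhoods_per_subdistrict)
  do.call(scenario_config, raw)
}

# Per-district substream: each district draws from its own seeded stream so
# that adding districts (or reordering stages) never perturbs earlier ones.
district_seed <- function(seed, index, stage) {
  as.integer((abs(seed) * 1000003 + index * 7919 + stage * 104729) %% 2147483629)
}

with_stream <- function(seed, index, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(district_seed(seed, index, stage))
  force(expr)
}

#' Generate a synthetic country
#'
#' Draws a full district table with known ground truth: hierarchy sizes from
#' their configured ranges, lognormal district populations, binomial insured
#' counts at the configured coverage, a poor/rich split whose poor share
#' rises as density falls, HCCs allocated by the configured policy and placed
#' across subdistricts, Poisson visit counts with per-category intensities
#' and income multipliers, and a cost made of fixed per-facility and
#' per-visit components scaled by the remoteness/scale elasticity.
#'
#' The poor/rich split partitions the insured exactly; districts in states
#' that do not report income data get `NA` income-stratified visits (the
#' totals are unaffected). Districts with no facility have zero visits and
#' zero cost.
#'
#' @param cfg A [scenario_config()].
#' @return A list with elements `districts` (a validated district tibble) and
#'   `ground_truth` (the config, its hash, and a per-district tibble of
#'   latent quantities: intended catchment category, density percentile, poor
#'   share, allocated HCCs, expected visit counts, cost multiplier).
#' @examples
#' sim <- simulate_country(scenario_config(seed = 7, n_states = 3,
#'                                         districts_per_state = 4))
#' sim$districts
#' sim$ground_truth$districts$intended_category
#' @export
simulate_country <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_total <- cfg$n_states * cfg$districts_per_state
  state_of <- rep(seq_len(cfg$n_states), each = cfg$districts_per_state)

  # stage 1: hierarchy and population, one substream per district
  base <- purrr::map_dfr(seq_len(n_total), function(i) {
    with_stream(cfg$seed, i, 1L, {
      r_sub <- cfg$subdistricts_per_district
      n_sub <- sample(r_sub[1]:r_sub[2], 1)
      r_nb <- cfg$neighborhoods_per_subdistrict
      n_nb <- sum(sample(r_nb[1]:r_nb[2], n_sub, replace = TRUE))
      pop <- max(50, round(rlnorm(1, cfg$population_meanlog,
                                  cfg$population_sdlog)))
      insured <- rbinom(1, pop, cfg$insurance_coverage)
      tibble(
        state_id = sprintf("S%02d", state_of[i]),
        district_id = sprintf("S%02d-D%03d", state_of[i],
                              (i - 1) %% cfg$districts_per_state + 1),
        n_subdistricts = n_sub,
        n_neighborhoods = n_nb,
        population_total = pop,
        insured_total = insured
      )
    })
  })

  # density percentile and income gradient (deterministic given stage 1)
  pct <- (rank(base$insured_total, ties.method = "first") - 0.5) / n_total
  poor_share <- pmin(0.95, pmax(
    0.05,
    cfg$poor_share_base + cfg$poor_share_density_slope * (1 - pct)
  ))
  insured_poor <- round(poor_share * base$insured_total)
  insured_rich <- base$insured_total - insured_poor

  # facility allocation (deterministic given stage 1)
  n_hcc <- allocate_hccs(cfg, base$insured_total, base$n_subdistricts)
  hcc_counts <- purrr::map2(n_hcc, base$n_subdistricts, place_hccs)
  intended <- intended_category(n_hcc, base$n_subdistricts)

  # stage 2: visits and cost, one substream per district
  group <- ifelse(intended == "neighborhood", "N", "MTN")
  mu_poor <- insured_poor * cfg$visit_prob[intended] *
    cfg$poor_visit_multiplier[group]
  mu_rich <- insured_rich * cfg$visit_prob[intended]
  visits <- purrr::map2_dfr(mu_poor, seq_len(n_total), function(mp, i) {
    with_stream(cfg$seed, i, 2L, {
      tibble(visits_poor = as.numeric(rpois(1, mp)),
             visits_rich = as.numeric(rpois(1, mu_rich[i])))
    })
  })
  visits_total <- visits$visits_poor + visits$visits_rich

  ref_insured <- stats::median(base$insured_total)
  remoteness <- (ref_insured / pmax(base$insured_total, 1))^
    cfg$remoteness_cost_elasticity
  cost_local <- (n_hcc * cfg$cost_fixed_per_hcc +
                   visits_total * cfg$cost_per_visit) * remoteness

  # income reporting mask, drawn once from the country-level stream
  missing_states <- with_stream(cfg$seed, 0L, 0L, {
    sort(sample(seq_len(cfg$n_states), cfg$income_missing_states))
  })
  income_present <- !(state_of %in% missing_states)

  districts <- base %>%
    mutate(
      insured_poor = insured_poor,
      insured_rich = insured_rich,
      hcc_counts = hcc_counts,
      visits_total = visits_total,
      visits_poor = dplyr::if_else(income_present, visits$visits_poor,
                                   NA_real_),
      visits_rich = dplyr::if_else(income_present, visits$visits_rich,
                                   NA_real_),
      cost_local = round(cost_local, 2),
      income_data_present = income_present
    ) %>%
    select(all_of(district_columns())) %>%
    validate_districts()

  ground_truth <- list(
    config = cfg,
    config_hash = scenario_hash(cfg),
    districts = tibble(
      district_id = districts$district_id,
      state_id = districts$state_id,
      intended_category = catchment_factor(intended),
      density_percentile = pct,
      poor_share = poor_share,
      n_hcc = n_hcc,
      mu_visits_poor = unname(mu_poor),
      mu_visits_rich = unname(mu_rich),
      remoteness_multiplier = remoteness
    )
  )

  list(districts = districts, ground_truth = ground_truth)
}

# Distribute the national HCC budget across districts.
allocate_hccs <- function(cfg, insured, n_sub) {
  budget <- cfg$hcc_budget %||%
    round(sum(insured) / cfg$insured_per_hcc_target)
  if (budget <= 0) {
    abort(sprintf("infeasible scenario: HCC budget is %d", budget))
  }

  switch(cfg$allocation_policy,
    density_proportional = {
      w <- pmax(insured, 1)^cfg$allocation_exponent
      snap_to_tier(budget * w / sum(w), n_sub)
    },
    equitable = {
      need <- sum(n_sub)
      if (budget < need) {
        abort(sprintf(
          "infeasible scenario: equitable policy needs %d HCCs (one per subdistrict) but the budget is %d",
          need, budget
        ))
      }
      n_sub + largest_remainder(budget - need, pmax(insured, 1))
    },
    per_capita_target = round(insured / cfg$insured_per_hcc_target)
  )
}

# Snap a continuous budget share to an administrative coverage tier: nothing,
# one district-level facility, one per subdistrict, or neighborhood-level
# surplus. Planners deploy coverage patterns, not fractional facilities.
snap_to_tier <- function(h, n_sub) {
  out <- integer(length(h))
  mid <- (1 + n_sub) / 2
  out[h >= 0.5] <- 1L
  out[h >= mid] <- n_sub[h >= mid]
  nb <- h >= n_sub + 0.5
  out[nb] <- as.integer(round(h[nb]))
  out
}

# Apportion `total` integer units proportionally to `w` (largest remainder).
largest_remainder <- function(total, w) {
  if (total == 0) return(integer(length(w)))
  q <- total * w / sum(w)
  base <- floor(q)
  short <- total - sum(base)
  extra <- integer(length(w))
  if (short > 0) {
    extra[order(q - base, decreasing = TRUE)[seq_len(short)]] <- 1L
  }
  as.integer(base + extra)
}

# Place a district's HCCs across its subdistricts: spread evenly once every
# subdistrict is covered, otherwise fill subdistricts first-come.
place_hccs <- function(n_hcc, n_sub) {
  n_hcc <- as.integer(n_hcc)
  if (n_hcc <= 0) return(integer(n_sub))
  if (n_hcc < n_sub) {
    return(as.integer(seq_len(n_sub) <= n_hcc))
  }
  base <- n_hcc %/% n_sub
  extra <- n_hcc %% n_sub
  as.integer(base + (seq_len(n_sub) <= extra))
}

intended_category <- function(n_hcc, n_sub) {
  dplyr::case_when(
    n_hcc == 0 ~ "zero",
    n_hcc < n_sub ~ "district",
    n_hcc == n_sub ~ "subdistrict",
    TRUE ~ "neighborhood"
  )
}

#' A small deterministic synthetic district table, for examples
#'
#' @return A validated district tibble (2 states, 3 districts each).
#' @export
synthetic_districts_example <- function() {
  simulate_country(scenario_config(seed = 42, n_states = 2,
                                   districts_per_state = 3))$districts
}
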