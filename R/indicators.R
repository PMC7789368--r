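#' Catchment-area distribution table
#'
#' Disaggregates the general characteristics of the country — total
#' population, insured population, insured poor, insured rich, number of
#' districts, number of HCCs — by catchment category, with counts and
#' row-percentages (each measure's percentages sum to 100 up to rounding).
#' This is the framework's "who / where" table: it shows how population mass
#' and facilities concentrate across catchment categories.
#'
#' @param districts A classified district table (see [classify_districts()]).
#' @param weight Optional name of a column giving the number of real districts
#'   each row aggregates (used when rows are category-level totals rather than
#'   individual districts, as in [table1_districts()]). Default: each row
#'   counts as one district.
#' @param totals Optional named numeric vector of published grand totals (per
#'   measure) to use as percentage denominators. Administrative sources
#'   sometimes publish a grand total that exceeds the sum of the category
#'   cells by an uncategorised remainder; supplying the published total
#'   reproduces the source's percentages (whose row then sums to slightly
#'   under 100). Default: denominators are the category sums.
#' @return A tibble of class `ce_distribution` with columns `measure`,
#'   `catchment_level`, `count`, `percent` and `total`; percentages are
#'   rounded half-up to 2 decimals.
#' @examples
#' distribution_table(table1_districts(), weight = "n_districts",
#'                    totals = table1_totals())
#' @export
distribution_table <- function(districts, weight = NULL, totals = NULL) {
  if (nrow(districts) == 0) abort("distribution_table: empty district table")
  if (!"catchment_level" %in% names(districts)) {
    abort("distribution_table: districts must be classified first (see classify_districts())")
  }

  d_weight <- if (is.null(weight)) {
    rep(1, nrow(districts))
  } else {
    districts[[weight]]
  }
  n_hcc <- vapply(districts$hcc_counts, function(h) sum(as.numeric(h)),
                  numeric(1))

  long <- tibble(
    catchment_level = rep(districts$catchment_level, 6L),
    measure = factor(
      rep(distribution_measures(), each = nrow(districts)),
      levels = distribution_measures()
    ),
    value = c(
      districts$population_total, districts$insured_total,
      districts$insured_poor, districts$insured_rich,
      d_weight, n_hcc
    )
  )

  out <- long %>%
    group_by(.data$measure, .data$catchment_level) %>%
    summarise(count = sum(.data$value, na.rm = TRUE), .groups = "drop_last") %>%
    tidyr::complete(
      catchment_level = catchment_factor(catchment_levels()),
      fill = list(count = 0)
    ) %>%
    mutate(total = sum(.data$count)) %>%
    ungroup()

  if (!is.null(totals)) {
    unknown <- setdiff(names(totals), distribution_measures())
    if (length(unknown) > 0) {
      abort(paste0("`totals` has unknown measure(s): ",
                   paste(unknown, collapse = ", ")))
    }
    idx <- match(as.character(out$measure), names(totals))
    out$total <- ifelse(is.na(idx), out$total, totals[idx])
  }

  out <- out %>%
    mutate(percent = round_half_up(100 * .data$count / .data$total, 2)) %>%
    arrange(.data$measure, dplyr::desc(.data$catchment_level)) %>%
    select("measure", "catchment_level", "count", "percent", "total")

  class(out) <- c("ce_distribution", class(out))
  out
}

#' @rdname distribution_table
#' @details `table1_totals()` returns the published grand totals matching
#'   [table1_districts()]; the published insured total exceeds the sum of its
#'   category cells by 13,484 uncategorised insured persons, so the published
#'   percentages only reproduce against these denominators.
#' @export
table1_totals <- function() {
  c(population_total = 37418999, insured_total = 16396484,
    insured_poor = 6530498, insured_rich = 5162421,
    districts = 189, hccs = 1313)
}

distribution_measures <- function() {
  c("population_total", "insured_total", "insured_poor", "insured_rich",
    "districts", "hccs")
}

#' Per-district utilization rate
#'
#' Annual insured visits per accessible insured person, computed per district:
#' `visits_total / insured_total`. Districts with zero insured have an
#' undefined rate, marked `NA` (never zero-imputed). Rates can exceed 1 —
#' visits are counted, not distinct visitors.
#'
#' @param districts A district table.
#' @return The input with a `utilization_rate` column appended.
#' @export
district_utilization_rate <- function(districts) {
  districts %>%
    mutate(utilization_rate = dplyr::if_else(
      .data$insured_total > 0,
      .data$visits_total / .data$insured_total,
      NA_real_
    ))
}

#' Catchment-area utilization rate indicators
#'
#' For each state and for the national pool, computes visits per accessible
#' insured person within the N (neighborhood) and MTN (more than neighborhood)
#' catchment groups, the geographic rate (all districts in scope pooled), and
#' the four income-stratified rates (poor/rich crossed with N/MTN).
#'
#' Income-stratified rates pool only districts that report income-stratified
#' visits (`income_data_present`), so missing income data is never treated as
#' zero utilization. A group with no districts, or zero accessible insured,
#' yields `NA` for that rate while the others are still computed. When both
#' group denominators are positive the geographic rate lies between the N and
#' MTN rates (it is their insured-weighted mean).
#'
#' @param districts A classified district table.
#' @param include_zero_in_mtn Should districts in the `zero` category (no
#'   facility at all) count toward the MTN group's visits and denominator?
#'   Default `TRUE`: zero-facility districts are an accessibility state of the
#'   MTN side, not an exclusion.
#' @return A tibble with one row per state plus a `"national"` row: columns
#'   `scope`, `n_districts`, `n_rate`, `mtn_rate`, `geographic_rate`,
#'   `poor_n_rate`, `poor_mtn_rate`, `rich_n_rate`, `rich_mtn_rate`.
#' @examples
#' sim <- simulate_country(paper_regime(seed = 1))
#' rates <- classify_districts(sim$districts) |> utilization_rates()
#' @export
utilization_rates <- function(districts, include_zero_in_mtn = TRUE) {
  if (!"catchment_level" %in% names(districts)) {
    abort("utilization_rates: districts must be classified first")
  }
  scopes <- c(sort(unique(districts$state_id)), "national")
  purrr::map_dfr(scopes, function(sc) {
    d <- if (sc == "national") districts else
      districts[districts$state_id == sc, ]
    scope_rates(d, sc, include_zero_in_mtn)
  })
}

scope_rates <- function(d, scope, include_zero_in_mtn) {
  is_n <- d$catchment_level == "neighborhood"
  is_mtn <- if (include_zero_in_mtn) !is_n else
    !is_n & d$catchment_level != "zero"
  inc <- d$income_data_present

  rate <- function(visits, insured, sel) {
    den <- sum(insured[sel], na.rm = TRUE)
    if (!any(sel) || den <= 0) return(NA_real_)
    sum(visits[sel], na.rm = TRUE) / den
  }

  tibble(
    scope = scope,
    n_districts = nrow(d),
    n_rate = rate(d$visits_total, d$insured_total, is_n),
    mtn_rate = rate(d$visits_total, d$insured_total, is_mtn),
    geographic_rate = rate(d$visits_total, d$insured_total,
                           rep(TRUE, nrow(d))),
    poor_n_rate = rate(d$visits_poor, d$insured_poor, is_n & inc),
    poor_mtn_rate = rate(d$visits_poor, d$insured_poor, is_mtn & inc),
    rich_n_rate = rate(d$visits_rich, d$insured_rich, is_n & inc),
    rich_mtn_rate = rate(d$visits_rich, d$insured_rich, is_mtn & inc)
  )
}

#' Cost of health-care services per capita, by catchment category
#'
#' Converts each category's total annual cost from local currency to USD at a
#' flat buying rate and divides by the insured population accessible in that
#' category. A category with zero accessible insured is undefined (`NA`),
#' never reported as zero; a category with insured but no spending is a true
#' 0.
#'
#' @param districts A classified district table with `cost_local`.
#' @param fx_rate Local-currency units per USD (default 7, a flat buying
#'   rate).
#' @return A tibble with columns `catchment_level`, `n_districts`,
#'   `insured_total`, `cost_local`, `cost_usd_per_capita`, ordered finest to
#'   coarsest.
#' @export
cost_per_capita <- function(districts, fx_rate = 7) {
  if (fx_rate <= 0) abort("`fx_rate` must be positive")
  if (!"catchment_level" %in% names(districts)) {
    abort("cost_per_capita: districts must be classified first")
  }
  districts %>%
    group_by(catchment_level = .data$catchment_level) %>%
    summarise(
      n_districts = dplyr::n(),
      insured_total = sum(.data$insured_total, na.rm = TRUE),
      cost_local = sum(.data$cost_local, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(cost_usd_per_capita = dplyr::if_else(
      .data$insured_total > 0,
      (.data$cost_local / fx_rate) / .data$insured_total,
      NA_real_
    )) %>%
    arrange(dplyr::desc(.data$catchment_level))
}

#' Insured-population density classes
#'
#' A district's insured density is its share (percent) of the state's total
#' insured population, binned into five classes: `< 20` very low, `20-39`
#' low, `40-59` moderate, `60-79` high, `80-100` very high (lower bounds
#' closed).
#'
#' `density_class()` is the vectorised primitive; `add_density_class()`
#' computes state totals from a district table and appends
#' `density_pct` and `density_class` columns.
#'
#' @param district_insured Insured persons in the district(s).
#' @param state_insured_total Insured persons in the whole state (must be
#'   positive).
#' @param districts A district table with `state_id` and `insured_total`.
#' @return `density_class()`: an ordered factor with levels
#'   `very_low < low < moderate < high < very_high`.
#' @examples
#' density_class(c(19, 20, 100), 100)
#' @export
density_class <- function(district_insured, state_insured_total) {
  if (any(state_insured_total <= 0)) {
    abort("`state_insured_total` must be positive")
  }
  pct <- 100 * district_insured / state_insured_total
  idx <- findInterval(pct, c(20, 40, 60, 80)) + 1L
  factor(density_levels()[idx], levels = density_levels(), ordered = TRUE)
}

density_levels <- function() {
  c("very_low", "low", "moderate", "high", "very_high")
}

#' @rdname density_class
#' @export
add_density_class <- function(districts) {
  districts %>%
    group_by(.data$state_id) %>%
    mutate(
      density_pct = 100 * .data$insured_total / sum(.data$insured_total),
      density_class = density_class(.data$insured_total,
                                    sum(.data$insured_total))
    ) %>%
    ungroup()
}
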