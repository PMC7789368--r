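#' Packaged worked example: national catchment-category totals
#'
#' A four-row district table in which each pseudo-district carries the
#' published national totals of one catchment category (population, insured,
#' insured poor, insured rich, number of real districts aggregated, HCCs) for
#' Sudan's national insurance scheme in 2016. Feeding it to
#' [distribution_table()] with `weight = "n_districts"` reproduces the
#' published distribution percentages; visit and cost fields are missing (the
#' source table does not carry them).
#'
#' @return A classified district tibble with an `n_districts` weight column.
#' @examples
#' distribution_table(table1_districts(), weight = "n_districts")
#' @export
table1_districts <- function() {
  d <- tibble(
    state_id = "SDN",
    district_id = c("neighborhood-total", "subdistrict-total",
                    "district-total", "zero-total"),
    n_subdistricts = c(1L, 217L, 2L, 1L),
    n_neighborhoods = c(2L, 217L, 2L, 1L),
    population_total = c(19240308, 10391005, 6884931, 902755),
    insured_total = c(11367127, 3320733, 1518913, 176227),
    insured_poor = c(3054274, 2068346, 1252875, 155003),
    insured_rich = c(3625538, 1249621, 266038, 21224),
    hcc_counts = list(1025L, rep(1L, 217L), c(71L, 0L), 0L),
    visits_total = NA_real_,
    visits_poor = NA_real_,
    visits_rich = NA_real_,
    cost_local = NA_real_,
    income_data_present = FALSE,
    n_districts = c(45, 70, 62, 12)
  )
  classify_districts(d)
}

#' Run the full disaggregation pipeline
#'
#' Executes validate -> classify -> indicators -> rank tests on a district
#' table and writes the complete, deterministic report bundle:
#' `districts_classified.csv`, `distribution_table.csv`,
#' `utilization_rates.csv`, `cost_indicator.csv`, `densities.csv`,
#' `tests.json` and `report.md`. The report is organised around the four
#' equity-monitoring questions: who is being left behind, why, where, and how
#' to protect them.
#'
#' The Mann-Whitney test compares district-level utilization rates between
#' the N and MTN groups; the Kruskal-Wallis test compares district-level
#' per-capita cost across the catchment categories. Either test is skipped
#' (recorded as such in `tests.json`) when its inputs are entirely missing or
#' a group is absent.
#'
#' @param input A district table, or the path of a districts CSV.
#' @param out_dir Output directory (created if needed); `NULL` computes
#'   everything without writing.
#' @param require_target_ratio,insured_per_hcc_target Passed to
#'   [classify_districts()].
#' @param include_zero_in_mtn Passed to [utilization_rates()].
#' @param fx_rate Local currency per USD for the cost indicator (default 7).
#' @param weight Optional districts-count weight column, as in
#'   [distribution_table()].
#' @param totals Optional published grand totals for the distribution table,
#'   as in [distribution_table()].
#' @return Invisibly, a list with `districts` (classified),
#'   `distribution`, `rates`, `cost`, `densities`, `tests` (list of
#'   `rank_test` or `NULL`), and `report` (character lines).
#' @examples
#' res <- run_pipeline(table1_districts(), out_dir = NULL,
#'                     weight = "n_districts")
#' res$distribution
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         require_target_ratio = FALSE,
                         insured_per_hcc_target = 10000,
                         include_zero_in_mtn = TRUE,
                         fx_rate = 7,
                         weight = NULL,
                         totals = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  districts <- stage("validate", {
    if (is.character(input)) read_districts(input) else
      validate_districts(input)
  })
  districts <- stage("classify", {
    classify_districts(districts,
                       require_target_ratio = require_target_ratio,
                       insured_per_hcc_target = insured_per_hcc_target)
  })
  distribution <- stage("indicators",
                        distribution_table(districts, weight, totals))
  rates <- stage("indicators", {
    utilization_rates(districts, include_zero_in_mtn = include_zero_in_mtn)
  })
  cost <- stage("indicators", cost_per_capita(districts, fx_rate = fx_rate))
  densities <- stage("indicators", {
    add_density_class(district_utilization_rate(districts)) %>%
      select("state_id", "district_id", "catchment_level", "n_mtn",
             "utilization_rate", "density_pct", "density_class")
  })
  tests <- stage("test", pipeline_tests(districts, fx_rate))
  report <- stage("report", {
    build_report(distribution, rates, cost, densities, tests)
  })

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_districts(districts, file.path(out_dir, "districts_classified.csv"))
      readr::write_csv(distribution,
                       file.path(out_dir, "distribution_table.csv"), na = "")
      readr::write_csv(rates, file.path(out_dir, "utilization_rates.csv"),
                       na = "")
      readr::write_csv(cost, file.path(out_dir, "cost_indicator.csv"),
                       na = "")
      readr::write_csv(densities, file.path(out_dir, "densities.csv"),
                       na = "")
      jsonlite::write_json(tests_json(tests),
                           file.path(out_dir, "tests.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
      writeLines(report, file.path(out_dir, "report.md"))
    })
  }

  invisible(list(
    districts = districts, distribution = distribution, rates = rates,
    cost = cost, densities = densities, tests = tests, report = report
  ))
}

pipeline_tests <- function(districts, fx_rate) {
  d <- district_utilization_rate(districts)
  d$cost_pc <- dplyr::if_else(
    d$insured_total > 0,
    (d$cost_local / fx_rate) / d$insured_total,
    NA_real_
  )

  mw <- NULL
  n_rates <- d$utilization_rate[d$n_mtn == "N"]
  mtn_rates <- d$utilization_rate[d$n_mtn == "MTN"]
  if (any(!is.na(n_rates)) && any(!is.na(mtn_rates))) {
    mw <- mann_whitney(n_rates, mtn_rates, labels = c("N", "MTN"))
  }

  kw <- NULL
  grp <- split(d$cost_pc, as.character(d$catchment_level))
  grp <- lapply(grp, function(v) v[!is.na(v)])
  if (sum(lengths(grp) > 0) >= 2) {
    kw <- kruskal_wallis(grp[order(match(names(grp), catchment_levels()),
                                   decreasing = TRUE)])
  }

  list(utilization_n_vs_mtn = mw, cost_per_capita_by_catchment = kw)
}

tests_json <- function(tests) {
  purrr::map(tests, function(t) {
    if (is.null(t)) return(NULL)
    list(
      test_name = t$test,
      statistic = unname(t$statistic),
      p_value = t$p_value,
      method = t$method,
      groups = purrr::pmap(t$groups, function(label, n, median, iqr) {
        list(label = label, n = n, median = median, iqr = iqr)
      })
    )
  })
}

md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "", format(round(x, digits), trim = TRUE,
                                  scientific = FALSE, drop0trailing = TRUE))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
}

build_report <- function(distribution, rates, cost, densities, tests) {
  test_lines <- function(t) {
    if (is.null(t)) return("Not computed: required inputs were missing.")
    c(
      sprintf("%s test (%s): %s = %.4g, p = %.4g.",
              t$test, t$method, names(t$statistic), t$statistic, t$p_value),
      "",
      md_table(t$groups)
    )
  }

  dens_summary <- densities %>%
    dplyr::count(.data$density_class, name = "n_districts")

  c(
    "# Catchment-area equity report",
    "",
    "Indicators disaggregated by the catchment category of each district's",
    "health-care centres (neighborhood / subdistrict / district / zero) and",
    "by the N vs MTN (more than neighborhood) contrast.",
    "",
    "## Who is being left behind?",
    "",
    "Distribution of population, insured population, income strata,",
    "districts and HCCs across catchment categories:",
    "",
    md_table(select(as_tibble(distribution), -"total")),
    "",
    "Utilization rates (annual visits per accessible insured person), by",
    "scope and group; income-stratified rates pool only districts reporting",
    "income data:",
    "",
    md_table(rates),
    "",
    "## Why are they being left behind?",
    "",
    "Cost of health-care services per capita (USD) by catchment category:",
    "",
    md_table(cost),
    "",
    "Insured-density classes of districts (district share of the state's",
    "insured population):",
    "",
    md_table(dens_summary),
    "",
    "## Where are they being left behind?",
    "",
    "Districts by catchment category:",
    "",
    md_table(dplyr::count(densities, .data$catchment_level,
                          name = "n_districts")),
    "",
    "## How to protect them from being left behind?",
    "",
    "Rank-based comparisons supporting reallocation decisions:",
    "",
    test_lines(tests$utilization_n_vs_mtn),
    "",
    test_lines(tests$cost_per_capita_by_catchment)
  )
}
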