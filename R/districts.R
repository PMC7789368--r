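#' District records
#'
#' The unit of analysis throughout the package is the administrative district.
#' A district table holds, per district: its position in the
#' state > district > subdistrict > neighbourhood hierarchy, total and insured
#' population, the poor/rich split of the insured, the placement of health-care
#' centres (HCCs) across its subdistricts, annual insured visit counts (overall
#' and by income stratum), and the annual cost of services in local currency.
#'
#' `district_columns()` returns the canonical column names;
#' `validate_districts()` checks every structural invariant and normalises
#' missing income fields; `read_districts()` / `write_districts()` round-trip
#' the delimited interchange format, in which the `hcc_counts` column is a
#' `';'`-joined list of per-subdistrict HCC counts and an empty cell means
#' missing.
#'
#' Invariants enforced by `validate_districts()`:
#' * all counts are non-negative; `n_subdistricts >= 1` and
#'   `n_neighborhoods >= n_subdistricts`;
#' * `insured_total <= population_total`;
#' * `insured_poor + insured_rich <= insured_total` (an uncategorised
#'   remainder is permitted; administrative sources often leave part of the
#'   insured population unassigned to an income stratum);
#' * `visits_poor + visits_rich <= visits_total`;
#' * `hcc_counts` has exactly `n_subdistricts` entries;
#' * when `income_data_present` is `FALSE`, the income-stratified visit
#'   counts are missing (`NA`), never zero-imputed.
#'
#' @param districts A data frame of district records.
#' @param path File path of a districts CSV.
#' @return `validate_districts()` returns the validated tibble (with
#'   `income_data_present` filled in); `read_districts()` returns a validated
#'   tibble; `write_districts()` returns `path` invisibly.
#' @examples
#' d <- tibble::tibble(
#'   state_id = "S01", district_id = "S01-D001",
#'   n_subdistricts = 2L, n_neighborhoods = 10L,
#'   population_total = 5000, insured_total = 2000,
#'   insured_poor = 900, insured_rich = 1100,
#'   hcc_counts = list(c(2L, 1L)),
#'   visits_total = 2600, visits_poor = 1400, visits_rich = 1200,
#'   cost_local = 70000, income_data_present = TRUE
#' )
#' validate_districts(d)
#' @name districts
NULL

#' @rdname districts
#' @export
district_columns <- function() {
  c(
    "state_id", "district_id", "n_subdistricts", "n_neighborhoods",
    "population_total", "insured_total", "insured_poor", "insured_rich",
    "hcc_counts", "visits_total", "visits_poor", "visits_rich",
    "cost_local", "income_data_present"
  )
}

csv_columns <- function() setdiff(district_columns(), "income_data_present")

#' @rdname districts
#' @export
validate_districts <- function(districts) {
  districts <- as_tibble(districts)
  if (nrow(districts) == 0) {
    abort("district table is empty: at least one district row is required")
  }

  required <- setdiff(district_columns(), "income_data_present")
  missing_cols <- setdiff(required, names(districts))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "district table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }

  if (!is.list(districts$hcc_counts)) {
    districts$hcc_counts <- parse_hcc_counts(districts$hcc_counts)
  }
  if (!"income_data_present" %in% names(districts)) {
    districts$income_data_present <-
      !is.na(districts$visits_poor) & !is.na(districts$visits_rich)
  }

  fail <- function(field, rows, why) {
    ids <- paste(districts$district_id[head(rows, 5)], collapse = ", ")
    abort(sprintf("invalid field `%s` (%s) in district(s): %s", field, why, ids))
  }
  bad <- function(x) !is.na(x) & x

  count_fields <- c(
    "n_subdistricts", "n_neighborhoods", "population_total", "insured_total",
    "insured_poor", "insured_rich", "visits_total", "visits_poor",
    "visits_rich", "cost_local"
  )
  for (f in count_fields) {
    i <- which(bad(districts[[f]] < 0))
    if (length(i) > 0) fail(f, i, "negative count")
  }

  i <- which(bad(districts$n_subdistricts < 1))
  if (length(i) > 0) fail("n_subdistricts", i, "must be >= 1")

  i <- which(bad(districts$n_neighborhoods < districts$n_subdistricts))
  if (length(i) > 0) {
    fail("n_neighborhoods", i, "fewer neighborhoods than subdistricts")
  }

  i <- which(bad(districts$insured_total > districts$population_total))
  if (length(i) > 0) fail("insured_total", i, "exceeds population_total")

  i <- which(bad(
    districts$insured_poor + districts$insured_rich > districts$insured_total
  ))
  if (length(i) > 0) {
    fail("insured_poor/insured_rich", i, "income strata sum exceeds insured_total")
  }

  i <- which(bad(
    districts$visits_poor + districts$visits_rich > districts$visits_total
  ))
  if (length(i) > 0) {
    fail("visits_poor/visits_rich", i, "income visit sum exceeds visits_total")
  }

  len_ok <- lengths(districts$hcc_counts) == districts$n_subdistricts
  if (any(!len_ok)) {
    fail("hcc_counts", which(!len_ok), "length must equal n_subdistricts")
  }
  neg_hcc <- vapply(
    districts$hcc_counts,
    function(h) anyNA(h) || any(h < 0),
    logical(1)
  )
  if (any(neg_hcc)) fail("hcc_counts", which(neg_hcc), "missing or negative entry")

  # districts that do not report income-stratified visits carry explicit
  # missing markers; never imputed as zero
  no_income <- !districts$income_data_present
  districts$visits_poor[no_income] <- NA_real_
  districts$visits_rich[no_income] <- NA_real_

  districts
}

parse_hcc_counts <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(parts) {
    as.integer(parts)
  })
}

format_hcc_counts <- function(x) {
  vapply(x, function(h) paste(format(h, trim = TRUE, scientific = FALSE),
                              collapse = ";"), character(1))
}

#' @rdname districts
#' @export
read_districts <- function(path) {
  districts <- readr::read_csv(
    path,
    col_types = readr::cols(
      state_id = readr::col_character(),
      district_id = readr::col_character(),
      n_subdistricts = readr::col_integer(),
      n_neighborhoods = readr::col_integer(),
      hcc_counts = readr::col_character(),
      population_total = readr::col_double(),
      insured_total = readr::col_double(),
      insured_poor = readr::col_double(),
      insured_rich = readr::col_double(),
      visits_total = readr::col_double(),
      visits_poor = readr::col_double(),
      visits_rich = readr::col_double(),
      cost_local = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  missing_cols <- setdiff(csv_columns(), names(districts))
  if (length(missing_cols) > 0) {
    abort(paste0(
      basename(path), " is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  districts$hcc_counts <- parse_hcc_counts(districts$hcc_counts)
  validate_districts(districts)
}

#' @rdname districts
#' @export
write_districts <- function(districts, path) {
  out <- as_tibble(districts)[, intersect(
    c(csv_columns(), setdiff(names(districts), district_columns())),
    names(districts)
  )]
  out$hcc_counts <- format_hcc_counts(districts$hcc_counts)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
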