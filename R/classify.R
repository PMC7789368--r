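#' Catchment categories
#'
#' A district's catchment category is the finest administrative level at which
#' its health-care centres (HCCs) provide coverage. Ordered from coarsest to
#' finest: `zero < district < subdistrict < neighborhood`. The binary contrast
#' used for all utilization comparisons collapses this to `N` (neighborhood)
#' versus `MTN` (more than neighborhood = subdistrict, district or zero).
#'
#' @return `catchment_levels()` returns the four level labels ordered from
#'   coarsest to finest.
#' @export
catchment_levels <- function() {
  c("zero", "district", "subdistrict", "neighborhood")
}

catchment_factor <- function(x) {
  factor(x, levels = catchment_levels(), ordered = TRUE)
}

#' Classify districts by the catchment level of their health-care centres
#'
#' Assigns each district the finest administrative level at which its HCC
#' placement provides coverage, from the per-subdistrict HCC counts alone:
#'
#' * no HCC at all -> `zero`;
#' * at least one HCC but some subdistrict uncovered -> `district` (the
#'   facility serves the whole district);
#' * every subdistrict covered and no surplus (total HCCs equals the number
#'   of subdistricts) -> `subdistrict`;
#' * every subdistrict covered with surplus HCCs -> `neighborhood` (each
#'   extra centre serves a group of neighbourhoods).
#'
#' Optionally (`require_target_ratio = TRUE`) the `neighborhood` label is only
#' kept when the district meets the health-map planning norm of at most
#' `insured_per_hcc_target` insured persons per HCC (default 10,000);
#' otherwise it degrades to `subdistrict`.
#'
#' @param districts A validated district table (see [validate_districts()]).
#' @param require_target_ratio Apply the insured-per-HCC planning gate to the
#'   `neighborhood` label? Default `FALSE`.
#' @param insured_per_hcc_target Planning norm: insured persons per HCC
#'   (default 10,000). Must be positive.
#' @return The input tibble with columns `n_hcc` (total HCCs),
#'   `catchment_level` (ordered factor) and `n_mtn` (`"N"`/`"MTN"`) appended.
#' @examples
#' d <- synthetic_districts_example()
#' classify_districts(d)
#' @seealso [binarize_catchment()], [distribution_table()]
#' @export
classify_districts <- function(districts,
                               require_target_ratio = FALSE,
                               insured_per_hcc_target = 10000) {
  if (insured_per_hcc_target <= 0) {
    abort("`insured_per_hcc_target` must be positive")
  }
  districts <- validate_districts(districts)

  n_hcc <- vapply(districts$hcc_counts, function(h) sum(as.numeric(h)),
                  numeric(1))
  all_covered <- vapply(districts$hcc_counts, function(h) all(h >= 1),
                        logical(1))

  level <- dplyr::case_when(
    n_hcc == 0 ~ "zero",
    !all_covered ~ "district",
    n_hcc == districts$n_subdistricts ~ "subdistrict",
    TRUE ~ "neighborhood"
  )

  if (require_target_ratio) {
    overloaded <- level == "neighborhood" &
      districts$insured_total / n_hcc > insured_per_hcc_target
    level[overloaded] <- "subdistrict"
  }

  districts$n_hcc <- n_hcc
  districts$catchment_level <- catchment_factor(level)
  districts$n_mtn <- binarize_catchment(districts$catchment_level)
  districts
}

#' Collapse catchment categories to the N / MTN contrast
#'
#' `neighborhood` maps to `"N"`; `subdistrict`, `district` and `zero` map to
#' `"MTN"` ("more than neighborhood").
#'
#' @param level A character vector or factor of catchment levels.
#' @return A factor with levels `"N"` and `"MTN"`.
#' @export
binarize_catchment <- function(level) {
  level <- as.character(level)
  stopifnot(all(level %in% catchment_levels()))
  factor(ifelse(level == "neighborhood", "N", "MTN"), levels = c("N", "MTN"))
}
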