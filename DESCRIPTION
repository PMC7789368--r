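Package: catchequity
Title: Catchment-Area Disaggregated Health-Equity Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring equity in the coverage and use of primary
    health-care centres when the only available data are district-level
    administrative tables. Districts are classified by the finest
    administrative level (neighbourhood, subdistrict, district, or none) at
    which their health-care centres provide coverage; utilization rates,
    income-stratified utilization rates, per-capita cost indicators and
    insured-density classes are disaggregated by that catchment category; and
    group differences are assessed with rank-based tests (Mann-Whitney,
    Kruskal-Wallis) carrying median/IQR summaries. A synthetic-country
    generator with known ground truth makes the whole pipeline testable
    without access to any national insurance information system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
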