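#' Plot a catchment-area distribution table
#'
#' Stacked percentage bars: how each measure (population, insured, income
#' strata, districts, HCCs) splits across catchment categories. A steep
#' contrast between the `insured_total` and `hccs` bars is the visual
#' signature of facility concentration.
#'
#' @param distribution A [distribution_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_distribution <- function(distribution, ...) {
  ggplot2::ggplot(
    distribution,
    ggplot2::aes(x = .data$measure, y = .data$percent,
                 fill = .data$catchment_level)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "YlGnBu", direction = -1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of national total",
                  fill = "catchment", title = "Catchment-area distribution") +
    ggplot2::theme_minimal()
}

#' @rdname plot_distribution
#' @param object A `ce_distribution` tibble, for the `autoplot` method.
#' @method autoplot ce_distribution
#' @export
autoplot.ce_distribution <- function(object, ...) plot_distribution(object, ...)

#' Plot utilization rates by scope
#'
#' Dumbbell-style comparison of the N, MTN and geographic utilization rates
#' for every state and the national pool.
#'
#' @param rates A [utilization_rates()] result.
#' @return A ggplot.
#' @export
plot_utilization <- function(rates) {
  long <- rates %>%
    select("scope", "n_rate", "mtn_rate", "geographic_rate") %>%
    tidyr::pivot_longer(-"scope", names_to = "group", values_to = "rate") %>%
    mutate(group = factor(.data$group,
                          levels = c("n_rate", "geographic_rate", "mtn_rate"),
                          labels = c("N", "geographic", "MTN")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rate, y = .data$scope,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::labs(x = "visits per accessible insured / year", y = NULL,
                  colour = NULL, title = "Catchment-area utilization rates") +
    ggplot2::theme_minimal()
}

#' Plot per-capita cost by catchment category
#'
#' @param cost A [cost_per_capita()] result.
#' @return A ggplot.
#' @export
plot_cost <- function(cost) {
  ggplot2::ggplot(cost, ggplot2::aes(x = .data$catchment_level,
                                     y = .data$cost_usd_per_capita)) +
    ggplot2::geom_col(fill = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "USD per insured person / year",
                  title = "Cost of services per capita by catchment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
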