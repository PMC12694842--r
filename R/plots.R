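#' Plot observed and expected monthly rates
#'
#' Observed monthly daily-average rates per 100,000 with the model-expected
#' curve; months excluded from fitting are marked.
#'
#' @param object a `trend_gamm`
#' @param ... unused
#' @return a ggplot
#' @method autoplot trend_gamm
#' @export
autoplot.trend_gamm <- function(object, ...) {
  dev <- predict_expected(object)
  dat <- dev %>%
    dplyr::mutate(date = as.Date(sprintf("%d-%02d-15", .data$year, .data$month)),
                  excluded = .data$year %in% object$exclude_years)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_rate, colour = .data$excluded),
                        size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_rate), linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "daily rate per 100,000",
                  colour = "excluded from fit",
                  title = paste("Observed vs expected:", object$series$category[1])) +
    ggplot2::theme_minimal()
}

#' Plot yearly rate ratios versus the reference year
#'
#' @param object a `year_rr`
#' @param ... unused
#' @return a ggplot
#' @method autoplot year_rr
#' @export
autoplot.year_rr <- function(object, ...) {
  ggplot2::ggplot(object$rr_table,
                  ggplot2::aes(x = .data$year, y = .data$rate_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high)) +
    ggplot2::labs(x = NULL, y = sprintf("rate ratio vs %d", object$ref_year)) +
    ggplot2::theme_minimal()
}

#' Plot coverage odds ratios
#'
#' @param object a `coverage_gamm`
#' @param ... unused
#' @return a ggplot forest-style plot of odds ratios by covariate level
#' @method autoplot coverage_gamm
#' @export
autoplot.coverage_gamm <- function(object, ...) {
  tab <- object$or_table %>%
    dplyr::mutate(label = paste(.data$covariate, .data$level, sep = ": "))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot yearly record and person retention
#'
#' @param retention a retention report from [retention_report()]
#' @return a ggplot
#' @export
plot_retention <- function(retention) {
  dat <- retention %>%
    dplyr::filter(.data$year != "undated") %>%
    dplyr::mutate(year = as.integer(.data$year)) %>%
    tidyr::pivot_longer(c("record_retention_pct", "person_retention_pct"),
                        names_to = "measure", values_to = "pct")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$pct,
                                    colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "% retained", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
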