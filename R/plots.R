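# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cost spectrum
#'
#' Pair-averaged transmission and informational cost as a function of
#' `ln(lambda)`; transmission cost falls and informational cost rises as
#' routing shifts from an unbiased walk to shortest paths.
#'
#' @param object A [cost_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cost_spectrum <- function(object, ...) {
  average_cost_curves(object) |>
    tidyr::pivot_longer(c("c_trans", "c_info"), names_to = "cost",
                        names_prefix = "c_", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(.data$ln_lambda, .data$value,
                                 colour = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cost, scales = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(trans = "#d66a84", info = "#4878a8"), guide = "none") +
    ggplot2::labs(x = expression(ln(lambda)), y = "pair-averaged cost")
}

#' Plot normalized cost curves
#'
#' Empirical-over-randomized cost ratios per `ln(lambda)`, with the
#' efficient windows (ratio below 1) shaded.
#'
#' @param object A [normalized_cost_curves()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.normalized_cost_spectrum <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("ratio_trans", "ratio_info"), names_to = "cost",
                        names_prefix = "ratio_", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(.data$ln_lambda, .data$ratio,
                                     colour = .data$cost)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(long, .data$ratio < 1),
                        size = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(trans = "#d66a84", info = "#4878a8"), name = "cost") +
    ggplot2::labs(x = expression(ln(lambda)),
                  y = "empirical / randomized cost")
}

#' Plot a regression ladder
#'
#' Cumulative and incremental variance explained per nested model.
#'
#' @param object A [hierarchical_regression()] ladder.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regression_ladder <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$model, .data$r.squared)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_col(ggplot2::aes(y = .data$delta.r.squared),
                      fill = "#4878a8") +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  subtitle = "grey: cumulative; blue: increment")
}
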