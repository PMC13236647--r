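# ggplot2 visualizations for the main result types.

#' @export
autoplot.pdp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$estimate - .data$band,
                   ymax = .data$estimate + .data$band),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = object$factor[1], y = "partial dependence",
      caption = "band: across-observation dispersion (not a confidence interval)"
    )
}

#' @export
autoplot.importance_ranking <- function(object, ...) {
  d <- mutate(object, factor = stats::reorder(.data$factor, .data$mean_abs_phi))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_abs_phi, y = .data$factor)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL)
}

#' @export
autoplot.dominant_factor_map <- function(object, ...) {
  ggplot2::ggplot(
    object$communities,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$dominant_factor)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "dominant factor")
}

#' Map LISA cluster classes
#'
#' @param lisa A [local_morans_i()] result.
#' @param coords Two-column matrix or data frame of unit coordinates.
#' @return A ggplot.
#' @export
plot_lisa <- function(lisa, coords) {
  stopifnot(inherits(lisa, "lisa_result"))
  d <- bind_cols(as_tibble(as.data.frame(coords))[, 1:2] |>
    rlang::set_names(c("x", "y")), as_tibble(lisa))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(
      HH = "#b2182b", LL = "#2166ac", HL = "#ef8a62", LH = "#67a9cf",
      ns = "grey80"
    )) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "LISA class")
}

#' Plot the model-comparison table
#'
#' @param comparison A [compare_models()] result.
#' @param metric One of `"r_squared"`, `"mae"`, `"rmse"`.
#' @return A ggplot.
#' @export
plot_model_comparison <- function(comparison, metric = "r_squared") {
  stopifnot(metric %in% c("r_squared", "mae", "rmse"))
  ggplot2::ggplot(
    comparison,
    ggplot2::aes(x = .data$scenario, y = .data[[metric]], fill = .data$model)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric, fill = "model")
}
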