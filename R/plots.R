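# ggplot2 visualisations for the main result types

#' Plot a species-flow matrix as a donor-by-recipient heatmap
#'
#' @param object A `colpress_flow` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colpress_flow <- function(object, ...) {
  edges <- export_chord(object)
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$recipient, y = .data$donor,
                                      fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Recipient region", y = "Donor (native) region",
                  fill = "Species flows",
                  title = sprintf("Interregional species flows (%s)",
                                  attr(object, "filter") %||% "all")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40,
                                                       hjust = 1))
}

#' Coefficient plot for conditionally averaged estimates
#'
#' @param object A `colpress_averaged` table.
#' @param ... Unused.
#' @return A ggplot object: estimates with 95 percent intervals,
#'   significant predictors highlighted.
#' @export
autoplot.colpress_averaged <- function(object, ...) {
  df <- as_tibble(object)
  df$predictor <- stats::reorder(df$predictor, df$estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$predictor,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$se,
      xmax = .data$estimate + 1.96 * .data$se)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "Standardized averaged estimate", y = NULL,
                  colour = "|z| ≥ 1.96") +
    ggplot2::theme_minimal()
}

#' Trade-breadth comparison plot
#'
#' Boxplots of trade breadth for established versus unestablished species
#' per class.
#'
#' @param breadth A [trade_breadth()] table.
#' @param metric Column to plot (default `n_trade_countries`).
#' @return A ggplot object.
#' @export
plot_breadth <- function(breadth, metric = "n_trade_countries") {
  assert_columns(breadth, c("class", "established", metric))
  df <- breadth
  df$group <- ifelse(df$established == 1, "established", "unestablished")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data[[metric]],
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}
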