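# ggplot2 views of the main result types.

pattern_palette <- function() {
  c(MONO_INC = "#1a9850", MONO_DEC = "#d73027", INC_DEC = "#fee08b",
    DEC_INC = "#4575b4", NOT_SIGNIFICANT = "grey80")
}

#' Plot a trend-pattern map
#'
#' Tile map of the five-class pattern labels.
#'
#' @param object a `pattern_map` from [classify_cube()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pattern_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pattern)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pattern_palette(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "pattern",
                  title = "Trend variation patterns") +
    ggplot2::theme_minimal()
}

#' Plot a decomposition
#'
#' Input, IMFs and residual as stacked facets.
#'
#' @param object an `imf_decomposition` from [emd()] or [eemd()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.imf_decomposition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(colour = "#2b5797") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL, title = "EEMD decomposition") +
    ggplot2::theme_minimal()
}

#' Plot driver importance
#'
#' Bar chart of mean |Shapley contribution| per driver.
#'
#' @param object a `shap_attribution` from [shapley_values()].
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.shap_attribution <- function(object, ...) {
  df <- importance_ranking(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_contribution,
                                   y = .data$feature)) +
    ggplot2::geom_col(fill = "#2b5797") +
    ggplot2::labs(x = "mean |contribution| (response units)", y = NULL,
                  title = "Driver importance") +
    ggplot2::theme_minimal()
}

#' Plot a zonal profile
#'
#' Per-bin median with interquartile ribbon against the zoning axis.
#'
#' @param profile a tibble from [zonal_profile()].
#' @return A ggplot.
#' @export
plot_zonal_profile <- function(profile) {
  df <- profile[profile$count > 0, ]
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "#2b5797", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "#2b5797") +
    ggplot2::labs(x = unique(df$axis), y = "multi-year mean",
                  title = "Zonal profile") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
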