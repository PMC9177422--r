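#' Plot annual habitat-area trajectories
#'
#' @param object A [habitat_series()].
#' @param ... Unused.
#' @return A ggplot of habitat area (ha) by year.
#' @method autoplot habitat_series
#' @export
autoplot.habitat_series <- function(object, ...) {
  ggplot2::ggplot(object$areas, ggplot2::aes(x = .data$year,
                                             y = .data$habitat_ha)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Year", y = "Habitat area (ha)",
                  title = object$species) +
    ggplot2::theme_minimal()
}

#' Plot a cover-class map for one year
#'
#' @param truth A [generate_landscape()] result.
#' @param year Year to draw.
#' @return A ggplot raster of cover classes.
#' @export
plot_landscape <- function(truth, year = max(truth$years)) {
  i <- match(year, truth$years)
  df <- tidyr::expand_grid(row = seq_len(truth$rows),
                           col = seq_len(truth$cols))
  df$class <- cover_classes()[truth$class_id[cbind(df$row, df$col, i)]]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      tolerant_old = "#1b5e20", regenerating = "#9ccc65",
      plantation = "#4fc3f7", non_forest = "#bdbdbd")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Cover classes, %d", year),
                  x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_void()
}

#' Plot posterior trend or covariate-effect intervals
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot of posterior means with 95% credible intervals.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$q2.5,
                                         xmax = .data$q97.5), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Posterior mean (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the beta-tuning AUC profile
#'
#' @param tuned Result of [tune_beta()].
#' @return A ggplot of training AUC against beta.
#' @export
plot_beta_profile <- function(tuned) {
  ggplot2::ggplot(tuned$results, ggplot2::aes(.data$beta, .data$train_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = tuned$beta, linetype = 2,
                        color = "#d95f02") +
    ggplot2::labs(x = "Regularization multiplier (beta)",
                  y = "Training AUC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
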