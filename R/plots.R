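#' Tile heatmap of a scored slide
#'
#' Draws the per-tile percent-positive map in image coordinates
#' (y-down), with the hot-spot tiles outlined.
#'
#' @param object A `slide_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slide_score
#' @export
autoplot.slide_score <- function(object, ...) {
  tiles <- object$tiles
  min_cells <- object$params$min_cells %||% 500
  k <- object$params$k %||% 5
  ranked <- tiles |>
    dplyr::filter(.data$total_cells >= min_cells) |>
    dplyr::arrange(dplyr::desc(.data$percent_positive),
                   dplyr::desc(.data$total_cells), .data$row, .data$col) |>
    utils::head(k)
  p <- ggplot2::ggplot(tiles) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x0_px, xmax = .data$x1_px,
      ymin = .data$y0_px, ymax = .data$y1_px,
      fill = .data$percent_positive), color = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "% Ki67+", na.value = "grey95") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Per-tile Ki67 positivity",
                  subtitle = sprintf(
                    "hot-spot index %.2f%%, whole-slide index %.2f%%",
                    object$summary$hot_spot_index,
                    object$summary$whole_slide_index)) +
    ggplot2::theme_minimal()
  if (nrow(ranked) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ranked,
      ggplot2::aes(xmin = .data$x0_px, xmax = .data$x1_px,
                   ymin = .data$y0_px, ymax = .data$y1_px),
      fill = NA, color = "red", linewidth = 0.6)
  }
  p
}

#' Distribution of cross-validated metrics
#'
#' Boxplots of the per-round confusion metrics of a [cross_validate()]
#' report.
#'
#' @param object A `ki67_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ki67_cv
#' @export
autoplot.ki67_cv <- function(object, ...) {
  object$rounds |>
    dplyr::filter(!.data$empty_round) |>
    tidyr::pivot_longer(
      c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
      names_to = "metric", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5,
                          outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Cross-validated risk-group prediction") +
    ggplot2::theme_minimal()
}

#' Variable-importance dot plot
#'
#' Mean %IncMSE per predictor with +/- one standard deviation over the
#' cross-validation rounds.
#'
#' @param cv A `ki67_cv`.
#' @return A ggplot.
#' @export
plot_importance <- function(cv) {
  stopifnot(inherits(cv, "ki67_cv"))
  imp <- dplyr::mutate(cv$importance,
                       predictor = stats::reorder(.data$predictor,
                                                  .data$mean_inc_mse_pct))
  ggplot2::ggplot(imp, ggplot2::aes(.data$mean_inc_mse_pct,
                                    .data$predictor)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$mean_inc_mse_pct - .data$sd_inc_mse_pct,
      xmax = .data$mean_inc_mse_pct + .data$sd_inc_mse_pct)) +
    ggplot2::labs(x = "%IncMSE (mean +/- sd)", y = NULL,
                  title = "Permutation variable importance") +
    ggplot2::theme_minimal()
}

#' Agreement scatter plot for paired scores
#'
#' Scatter of two paired measurement series with the identity line and
#' the Pearson r / Lin's CCC annotation.
#'
#' @param data Data frame of paired scores.
#' @param x,y Unquoted column names.
#' @return A ggplot.
#' @export
plot_concordance <- function(data, x, y) {
  stats_row <- concordance(data, {{ x }}, {{ y }})
  ggplot2::ggplot(data, ggplot2::aes({{ x }}, {{ y }})) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      title = "Agreement between paired Ki67 scores",
      subtitle = sprintf("Pearson r = %.3f, Lin's CCC = %.3f, n = %d",
                         stats_row$r, stats_row$ccc, stats_row$n)) +
    ggplot2::theme_minimal()
}
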