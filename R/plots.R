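# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_line
#'   geom_abline labs scale_fill_viridis_c theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot the grid-search distance surface
#'
#' Heatmap of the Euclidean distance over the (alpha, n) grid, with the
#' retained top combinations marked.
#'
#' @param object A `qp_grid_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qp_grid_search <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$alpha, y = .data$n, fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c(direction = -1) +
    geom_point(data = object$top, aes(x = .data$alpha, y = .data$n),
               inherit.aes = FALSE, shape = 21, fill = "white", size = 2) +
    labs(x = expression(alpha), y = "n",
         fill = "distance\n(rating units)",
         title = "Quality-proxy calibration surface") +
    theme_minimal()
}

#' Plot a training history
#'
#' Training and validation MAE per epoch, with the best epoch marked.
#'
#' @param object A `wine_dnn`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wine_dnn <- function(object, ...) {
  hist_long <- object$history |>
    tidyr::pivot_longer(c("loss", "val_loss"), names_to = "series",
                        values_to = "mae") |>
    filter(is.finite(.data$mae))
  ggplot(hist_long, aes(x = .data$epoch, y = .data$mae, colour = .data$series)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    labs(x = "epoch", y = "MAE (rating units)", colour = NULL,
         title = paste0("Training history (", object$spec$name, ")")) +
    theme_minimal()
}

#' Observed versus proxy quality per wine
#'
#' Scatter of each model column of a [quality_report()] against the observed
#' perceived quality, with the identity line.
#'
#' @param report A tibble from [quality_report()].
#' @return A ggplot.
#' @export
plot_quality_report <- function(report) {
  long <- report |>
    tidyr::pivot_longer(-c("wine_id", "observed"),
                        names_to = "model", values_to = "proxy")
  ggplot(long, aes(x = .data$observed, y = .data$proxy)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point() +
    facet_wrap(~model) +
    labs(x = "perceived quality (panel mean, 1-10)",
         y = "quality proxy",
         title = "Quality proxy vs perceived quality") +
    theme_minimal()
}
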