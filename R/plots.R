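#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a confusion matrix
#'
#' @param object A `cell_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cell_confusion
#' @export
autoplot.cell_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(attr(object, "labels"))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4477aa",
                                 guide = "none") +
    ggplot2::labs(x = "Predicted", y = "Ground truth") +
    ggplot2::theme_minimal()
}

#' Render a synthetic smear scene
#'
#' @param object A `smear_scene` from [generate_scene()].
#' @param ... Unused.
#' @return A ggplot showing the grayscale image.
#' @method autoplot smear_scene
#' @export
autoplot.smear_scene <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Predicted vs observed consensus accuracy
#'
#' Dot plot of the per-class gap between the independence-model estimate
#' and the observed consensus accuracy.
#'
#' @param comparison Output of [compare_estimate_vs_observed()].
#' @return A ggplot.
#' @export
plot_estimate_gap <- function(comparison) {
  df <- comparison |>
    tidyr::pivot_longer(c("acc_estimated", "acc_observed"),
                        names_to = "kind", values_to = "accuracy") |>
    dplyr::mutate(kind = ifelse(.data$kind == "acc_estimated",
                                "estimated (independence)", "observed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$accuracy,
                                   color = .data$kind)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$class), color = "grey60") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Consensus accuracy", color = NULL) +
    ggplot2::theme_minimal()
}

#' Worker accuracy against labeling volume
#'
#' Scatter of per-worker accuracy vs number of cells classified, with the
#' least-squares line from [worker_volume_regression()].
#'
#' @param workers Tibble from [worker_accuracy()].
#' @return A ggplot.
#' @export
plot_worker_volume <- function(workers) {
  ggplot2::ggplot(workers, ggplot2::aes(x = .data$n_classified,
                                        y = .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "#4477aa") +
    ggplot2::labs(x = "Cells classified", y = "Worker accuracy") +
    ggplot2::theme_minimal()
}
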