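# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fundus image or contour map as a raster
#'
#' @param object A `labeled_image` or `contour_map`.
#' @param ... Unused.
#' @method autoplot labeled_image
#' @export
autoplot.labeled_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$fill <- grDevices::rgb(px[, , 1][as.matrix(df[, 1:2])] / 255,
                            px[, , 2][as.matrix(df[, 1:2])] / 255,
                            px[, , 3][as.matrix(df[, 1:2])] / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$id, " (", object$label, ", ",
                                 object$source, ")")) +
    ggplot2::theme_void()
}

#' @rdname autoplot.labeled_image
#' @method autoplot contour_map
#' @export
autoplot.contour_map <- function(object, ...) {
  e <- object$edges
  df <- tidyr::expand_grid(row = seq_len(nrow(e)), col = seq_len(ncol(e)))
  df$on <- as.vector(e) == 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$on)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "white", `FALSE` = "black"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Training-history curves for a classifier
#'
#' @param object A trained `fv_cavit`.
#' @param ... Unused.
#' @method autoplot fv_cavit
#' @export
autoplot.fv_cavit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Loss traces for a CVGAN
#'
#' @param object A `fv_cvgan` with training history.
#' @param ... Unused.
#' @method autoplot fv_cvgan
#' @export
autoplot.fv_cvgan <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"step",
                           names_to = "loss", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map of a metric report
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  cm <- object$cm
  df <- tidyr::expand_grid(true = rownames(cm), predicted = colnames(cm))
  df$n <- as.vector(t(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
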