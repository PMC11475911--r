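# ggplot2 visualization of deconvolution and imputation results.

#' Spatial map of estimated cell-type proportions
#'
#' One panel per cell type, spots coloured by proportion.
#'
#' @param fit a `spot_deconv` object (or anything [tidy()]-able to spot /
#'   x / y / cell_type / proportion columns).
#' @param cell_types subset of cell types to show (default all).
#' @return a ggplot object.
#' @export
plot_proportions <- function(fit, cell_types = NULL) {
  df <- if (is.data.frame(fit)) fit else tidy(fit)
  if (!is.null(cell_types)) df <- df[df$cell_type %in% cell_types, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$proportion)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "proportion") +
    ggplot2::theme_minimal()
}

#' @rdname plot_proportions
#' @param object a `spot_deconv` object.
#' @param ... passed to [plot_proportions()].
#' @export
autoplot.spot_deconv <- function(object, ...) plot_proportions(object, ...)

#' Spatial map of the dominant cell type per spot
#'
#' @param fit a `spot_deconv` object.
#' @return a ggplot object.
#' @export
plot_dominant <- function(fit) {
  df <- data.frame(x = fit$coords$x, y = fit$coords$y,
                   dominant = dominant_type(fit$theta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$dominant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "dominant type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
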