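#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an area-change curve
#'
#' @param object An `area_series` tibble.
#' @param troughs Optional trough frame numbers to mark.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.area_series <- function(object, troughs = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$area)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "frame", y = "projected area (px)",
                  title = "Cell area change curve") +
    ggplot2::theme_minimal()
  if (!is.null(troughs)) {
    p <- p + ggplot2::geom_vline(xintercept = troughs, linetype = "dashed",
                                 colour = "firebrick", alpha = 0.6)
  }
  p
}

#' Plot a rotation result: smoothed area curve with detected troughs
#'
#' @param object A `rotation_result` carrying its series attribute.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.rotation_result <- function(object, ...) {
  series <- attr(object, "series")
  if (is.null(series)) rlang::abort("result carries no area series to plot.")
  autoplot.area_series(series, troughs = object$trough_frames) +
    ggplot2::labs(subtitle = sprintf(
      "%.1f rpm (max dev %.1f) over %d cycles, symmetry factor %d",
      object$mean_rpm, object$max_deviation_rpm, object$n_cycles,
      object$symmetry_factor))
}

#' Plot a motion trajectory in image coordinates
#'
#' The row axis is reversed so the plot matches image orientation.
#'
#' @param object A `trajectory` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$frame), size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = "Motion trajectory of the cell of interest") +
    ggplot2::theme_minimal()
}
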