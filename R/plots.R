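#' Plot a feature layer
#'
#' Raster plot of a band image or correlation map in the rainbow pseudo
#' colors customary in chemical imaging (red high, green medium, blue low).
#'
#' @param object A `feature_layer`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.feature_layer <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colors = c("blue", "cyan", "green", "yellow", "red"),
      limits = c(0, 255), name = "value"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s)", object$name, object$kind),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation
#'
#' @param object A `segmentation_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.segmentation_result <- function(object, ...) {
  d <- pixel_grid(nrow(object$labels), ncol(object$labels))
  d$segment <- factor(flatten_image(object$labels))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$segment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "segment") +
    ggplot2::theme_minimal()
}

#' Plot per-segment gray-value histograms
#'
#' Normalized histograms of the co-registered CT gray values, one panel
#' per segment.
#'
#' @param report A `crossmodal_report`.
#' @return A ggplot.
#' @export
plot_segment_histograms <- function(report) {
  stopifnot(inherits(report, "crossmodal_report"))
  ggplot2::ggplot(report$histograms,
                  ggplot2::aes(.data$gray, .data$prop)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~segment, scales = "free_y") +
    ggplot2::labs(x = "gray value (8 bit)", y = "relative count") +
    ggplot2::theme_minimal()
}

#' Plot per-segment box statistics of gray values
#'
#' Box plots of the CT gray values per segment, whiskers at the most
#' extreme points within 1.5 IQR of the box.
#'
#' @param report A `crossmodal_report`.
#' @return A ggplot.
#' @export
plot_segment_boxes <- function(report) {
  stopifnot(inherits(report, "crossmodal_report"))
  b <- report$box_stats
  ggplot2::ggplot(b, ggplot2::aes(x = factor(.data$segment))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q25,
                   middle = .data$median, upper = .data$q75,
                   ymax = .data$whisker_hi),
      stat = "identity"
    ) +
    ggplot2::labs(x = "segment", y = "gray value (8 bit)") +
    ggplot2::theme_minimal()
}
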