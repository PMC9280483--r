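#' Plot a repeat-length histogram with its called peaks
#'
#' Bar plot of read counts per repeat length for one sample x marker, with
#' retained peaks marked. A companion to the peak caller for eyeballing why a
#' marker was called the way it was.
#'
#' @param histogram Depth-table tibble for one sample x marker.
#' @param peaks Optional `msi_peaks` object to overlay.
#' @return A ggplot object.
#' @export
plot_marker_histogram <- function(histogram, peaks = NULL) {
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$repeat_length, y = .data$count)) +
    ggplot2::geom_col(fill = "grey55", width = 0.9) +
    ggplot2::labs(x = "repeat length (bp)", y = "read count") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = as_tibble(peaks),
                                 ggplot2::aes(xintercept = .data$position),
                                 linetype = "dashed", color = "firebrick")
  }
  if (nrow(histogram) > 0 && !is.na(histogram$marker[1])) {
    p <- p + ggplot2::ggtitle(paste0(histogram$marker[1],
                                     if (!is.na(histogram$tissue[1]))
                                       paste0(" (", histogram$tissue[1], ")")
                                     else ""))
  }
  p
}

#' @describeIn find_peaks Plot the peak set over its relative heights.
#' @param object An `msi_peaks` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.msi_peaks <- function(object, ...) {
  hp <- attr(object, "hyperparameters")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$relative_height)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = hp$r_h, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "repeat length (bp)", y = "relative height",
                  title = "Retained peaks",
                  subtitle = paste0("smoothing=", hp$smoothing,
                                    ", r_h=", hp$r_h)) +
    ggplot2::theme_minimal()
}

#' @describeIn grid_search Plot the loss surface: diff against threshold,
#'   one line per smoothing option.
#' @param object An `msi_tuning` object.
#' @exportS3Method ggplot2::autoplot
autoplot.msi_tuning <- function(object, ...) {
  grid <- mutate(object$grid,
                 smoothing = ifelse(.data$smoothing, "smoothing", "no smoothing"))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$r_h, y = .data$diff,
                                     color = .data$smoothing)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "peak height threshold (r_h)", y = "diff loss",
                  color = NULL) +
    ggplot2::theme_minimal()
}
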