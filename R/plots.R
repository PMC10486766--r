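#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_rect geom_tile
#'   geom_text geom_point geom_abline labs scale_fill_gradient2 theme_minimal
#'   annotate
#' @export
ggplot2::autoplot

#' Plot a force curve with its TPA segmentation
#'
#' @param object A `force_curve`.
#' @param segmentation Optional `cycle_segmentation`; shaded compression and
#'   adhesion windows are drawn when supplied.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_curve <- function(object, segmentation = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time, y = .data$force)) +
    geom_line(linewidth = 0.4) +
    labs(x = "time (s)", y = "force (gf)") +
    theme_minimal()
  if (!is.null(segmentation)) {
    shade <- function(bounds, fill) {
      annotate("rect", xmin = bounds[1], xmax = bounds[2],
               ymin = -Inf, ymax = Inf, alpha = 0.15, fill = fill)
    }
    p <- p + shade(segmentation$bounds$cycle1, "steelblue") +
      shade(segmentation$bounds$cycle2, "seagreen")
    if (!is.null(segmentation$bounds$adhesion)) {
      p <- p + shade(segmentation$bounds$adhesion, "firebrick")
    }
  }
  p
}

#' Heatmap of a trait correlation matrix
#'
#' @param object A `trait_cor` from [trait_correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_cor <- function(object, ...) {
  ggplot(object, aes(x = .data$trait1, y = .data$trait2, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                         mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' Overlay the yellow-class mask on image coordinates
#'
#' @param mask A `yellow_mask`.
#' @return A ggplot raster of the binary classification (yellow class in
#'   goldenrod).
#' @export
plot_yellow_mask <- function(mask) {
  stopifnot(inherits(mask, "yellow_mask"))
  d <- dim(mask$mask)
  df <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    yellow = as.vector(mask$mask)
  )
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$yellow)) +
    geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "goldenrod2")) +
    labs(x = NULL, y = NULL, fill = "yellow class",
         title = sprintf("yellow area: %.2f%%",
                         100 * mask$n_yellow / mask$n_total)) +
    theme_minimal()
}

#' Calibration plot of predicted vs observed eating-quality scores
#'
#' @param data Data frame with observed and predicted columns.
#' @param truth,estimate Column names (defaults `"IVOE"`, `".pred"`).
#' @return A ggplot with the identity line.
#' @export
plot_calibration <- function(data, truth = "IVOE", estimate = ".pred") {
  ggplot(data, aes(x = .data[[estimate]], y = .data[[truth]])) +
    geom_point(alpha = 0.5) +
    geom_abline(linetype = 2) +
    labs(x = "predicted IVOE", y = "observed IVOE") +
    theme_minimal()
}
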