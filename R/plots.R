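# ggplot2 displays for the main result types.

#' Plot a time-activity curve with its fit
#'
#' @param object An `fdg_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fdg_fit <- function(object, ...) {
  df <- tibble(time_min = object$schedule$mid_min,
               observed = object$tac, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), shape = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "Time (min)", y = "Activity concentration",
                  title = "FDG tissue curve and model fit")
}

#' Plot a LOWESS relationship curve with its confidence band
#'
#' @param object A `lowess_curve`.
#' @param show_sample Overlay the sampled voxels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lowess_curve <- function(object, show_sample = TRUE, ...) {
  g <- ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x))
  if (show_sample) {
    g <- g + ggplot2::geom_point(data = object$sample,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 alpha = 0.15, size = 0.4)
  }
  if (any(is.finite(object$curve$lwr))) {
    g <- g + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr,
                                               ymax = .data$upr),
                                  fill = "grey70", alpha = 0.5)
  }
  g + ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::labs(x = "x", y = "smoothed y",
                  title = "Voxel-wise LOWESS relationship")
}

#' Plot regional medians with interquartile ranges
#'
#' @param rt A region table from [region_table()].
#' @param variables Variables to show (default all present).
#' @return A ggplot.
#' @export
plot_region_medians <- function(rt, variables = unique(rt$variable)) {
  df <- rt[rt$variable %in% variables, ]
  df$region <- factor(df$region, levels = REGION_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median (IQR)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
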