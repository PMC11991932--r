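#' Plot the distribution of signed measurement differences
#'
#' Boxplots of `measured - true` per method, faceted by stone density --
#' negative medians mean underestimation. Accepts raw records or the output
#' of [signed_differences()].
#'
#' @param records Measurement records.
#' @return A ggplot object.
#' @export
plot_signed_differences <- function(records) {
  sd_tbl <- if (inherits(records, "signed_differences")) records else
    signed_differences(records)
  ggplot2::ggplot(sd_tbl,
                  ggplot2::aes(x = .data$method, y = .data$signed_diff,
                               fill = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~density_hu, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "measured - true size (mm)",
                  title = "Measurement differences from actual stone size") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.signed_differences <- function(object, ...) {
  plot_signed_differences(object)
}

#' Plot MAE by method and density
#'
#' @param mae A tibble from [mae_table()] (or a `stone_eval`).
#' @return A ggplot object.
#' @export
plot_mae <- function(mae) {
  if (inherits(mae, "stone_eval")) mae <- mae$mae
  ggplot2::ggplot(mae,
                  ggplot2::aes(x = factor(.data$density_hu), y = .data$mae,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mae - .data$sd, ymax = .data$mae + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE) +
    ggplot2::labs(x = "stone density (HU)", y = "mean absolute error (mm)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stone_eval <- function(object, ...) plot_mae(object)

#' Display one axial slice of a CT volume
#'
#' Renders a slice through a display window as a grey raster, with optional
#' overlay of measured edge points.
#'
#' @param vol A [ct_volume()].
#' @param slice Slice index (z).
#' @param window A [window_setting()] or preset name. Default `"bone"`.
#' @param points Optional `(y_mm, x_mm)` matrix of edge points to overlay.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice, window = "bone", points = NULL) {
  assert_ct_volume(vol)
  img <- apply_window(vol$voxels[slice, , , drop = TRUE], window)
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- img[cbind(df$y, df$x)]
  df$y_mm <- (df$y - 1) * vol$spacing[2]
  df$x_mm <- (df$x - 1) * vol$spacing[3]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(points) && nrow(points) > 0) {
    pd <- tibble::tibble(y_mm = points[, 1], x_mm = points[, 2])
    p <- p + ggplot2::geom_point(data = pd,
                                 ggplot2::aes(.data$x_mm, .data$y_mm),
                                 inherit.aes = FALSE, colour = "red",
                                 size = 0.5)
  }
  p
}
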