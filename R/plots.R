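# ggplot2 presentation layer for the fitted objects and rasters.

#' @describeIn fit_allometry log-log scatter of sqrt(area) against ITD with
#'   the fitted power law.
#' @param object a `dra_allometry` fit.
#' @param ... unused.
#' @export
autoplot.dra_allometry <- function(object, ...) {
  df <- object$data
  df$sqrt_area <- sqrt(df$area_mm2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$itd_mm, y = .data$sqrt_area)) +
    ggplot2::geom_point(shape = 17, size = 2) +
    ggplot2::geom_line(
      data = tibble(
        itd_mm = exp(seq(min(df$log_itd), max(df$log_itd), length.out = 50))
      ) |>
        dplyr::mutate(sqrt_area = exp(object$intercept) * .data$itd_mm^object$slope),
      linewidth = 0.4, colour = "grey30"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "inter-tegular distance (mm)",
      y = expression(sqrt(area) ~ "(mm)"),
      title = sprintf("slope %.3f (se %.3f), t(%d) = %.3f, p = %.3g",
                      object$slope, object$slope_se, object$df,
                      object$t_stat, object$p_value)
    ) +
    ggplot2::theme_classic()
}

#' @describeIn region_comparison boxplot of the measurements per region
#'   with compact-letter annotations (matching letters = not significantly
#'   different).
#' @param object a `dra_region_comparison`.
#' @param ... unused.
#' @export
autoplot.dra_region_comparison <- function(object, ...) {
  df <- object$data
  tops <- dplyr::summarise(dplyr::group_by(df, .data$region),
                           y = max(.data$value_um), .groups = "drop")
  lab <- dplyr::left_join(object$letters, tops, by = "region")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value_um)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = 1) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(y = .data$y * 1.05, label = .data$letters),
                       size = 4) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s %s (µm)", object$structure,
                              object$dimension)) +
    ggplot2::theme_classic()
}

#' Display a virtual slice or rendered view
#'
#' @param img matrix from [extract_slice()] or [render_view()]; `NA`
#'   samples (outside the volume) are shown blank.
#' @return a ggplot object.
#' @export
plot_slice <- function(img) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.numeric(img)[(df$col - 1L) * nrow(img) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
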