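#' Plot a scan stream as a height raster
#'
#' Height-coloured view of the stream (along-track on x, lateral on y),
#' the standard way to eyeball row plots, ground undulation and no-return
#' gaps in a captured column.
#'
#' @param object A [scan_stream()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_stream <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$odometer_mm, y = .data$lateral_mm,
                               fill = .data$height_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "along-track (mm)", y = "lateral (mm)",
                  fill = "height (mm)")
}

#' Plot a rasterized canopy surface
#'
#' @param object A `surface_grid` from [rasterize_surface()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surface_grid <- function(object, ...) {
  df <- tidyr::expand_grid(x = object$x_mm, y = object$y_mm)
  df$h_plus <- as.vector(t(object$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$h_plus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "along-track (mm)", y = "lateral (mm)",
                  fill = "h+ (mm)")
}

#' Plot an LV-yield calibration fit
#'
#' @param object An `lv_fit` from [linear_fit()].
#' @param ... Unused.
#' @return A ggplot of the observations with the fitted line.
#' @export
autoplot.lv_fit <- function(object, ...) {
  df <- tibble(x = object$model$model$xv, y = object$model$model$yv)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$y_intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "fresh weight (g/row)", y = "LiDAR Volume",
                  subtitle = sprintf("R² = %.3f, X-intercept = %.1f g",
                                     object$r2, object$x_intercept))
}

#' Plot a growth series
#'
#' @param object A `growth_series` from [growth_series()].
#' @param ... Unused.
#' @return A ggplot of yield over time with per-interval RGR labels.
#' @export
autoplot.growth_series <- function(object, ...) {
  pts <- tibble(t = c(object$t1[1], object$t2),
                y = c(object$y1[1], object$y2))
  ggplot2::ggplot(pts, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "days of regrowth", y = "yield / LV")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
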