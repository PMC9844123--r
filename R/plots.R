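#' Scatter plot of events in a feature plane with optional gate overlay
#'
#' The default view is the deformation-size plane familiar from
#' deformability-cytometry scatter plots; `y = brightness_au` gives the
#' brightness-size plane used for neutrophil/platelet gating.
#'
#' @param events event tibble.
#' @param g optional [gate()] drawn as a rectangle/polygon overlay.
#' @param x,y feature column names (defaults `area_um2`, `deformation`).
#' @param colour optional column mapped to point colour (e.g. `label`).
#' @return a ggplot object.
#' @export
plot_events <- function(events, g = NULL, x = "area_um2", y = "deformation",
                        colour = NULL) {
  p <- ggplot2::ggplot(events, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    (if (!is.null(colour))
      ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                          alpha = 0.4, size = 0.8)
     else ggplot2::geom_point(alpha = 0.4, size = 0.8)) +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
  if (!is.null(g)) {
    if (!is.null(g$polygon) && x == "area_um2" && y == "deformation") {
      poly <- rbind(g$polygon, g$polygon[1, ])
      p <- p + ggplot2::geom_path(data = poly,
                                  ggplot2::aes(x = .data$area_um2, y = .data$deformation),
                                  colour = "red", linewidth = 0.6)
    } else {
      xr <- if (x == "area_um2") g$area_range else if (x == "brightness_au") g$brightness_range
      yr <- if (y == "deformation" && !is.null(g$deformation_max)) c(0, g$deformation_max)
      else if (y == "brightness_au") g$brightness_range
      if (!is.null(xr) || !is.null(yr)) {
        lim <- function(r, v) if (is.null(r)) range(v, na.rm = TRUE) else r
        xr <- lim(xr, events[[x]]); yr <- lim(yr, events[[y]])
        p <- p + ggplot2::annotate("rect", xmin = xr[1], xmax = xr[2],
                                   ymin = yr[1], ymax = yr[2],
                                   colour = "red", fill = NA, linewidth = 0.6)
      }
    }
  }
  p
}

#' Kernel-density curve plot
#'
#' @param values numeric sample.
#' @param bandwidth optional bandwidth, see [kde_density()].
#' @param xlab axis label.
#' @return a ggplot object.
#' @export
plot_kde <- function(values, bandwidth = NULL, xlab = "value") {
  curve <- kde_density(values, bandwidth)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$value, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Purity/recovery vs concentration curves
#'
#' @param object a `concentration_sweep` from [purity_vs_concentration()].
#' @param ... unused.
#' @return a ggplot object with per-concentration means and replicate
#'   points for target purity and recovery.
#' @export
autoplot.concentration_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("tp", "recovery"),
                              names_to = "metric", values_to = "percent")
  long$metric <- dplyr::recode(long$metric, tp = "target purity",
                               recovery = "recovery")
  summ <- long |>
    dplyr::group_by(.data$concentration, .data$metric) |>
    dplyr::summarise(percent = mean(.data$percent), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$concentration / 1e6,
                                     y = .data$percent,
                                     colour = .data$metric)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = summ) +
    ggplot2::geom_hline(yintercept = 92, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "sample concentration (million cells/ml)", y = "%") +
    ggplot2::theme_minimal()
}

#' Render a frame as a ggplot raster
#'
#' @param object a `frame_stack`.
#' @param frame frame index (default 1).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.frame_stack <- function(object, frame = 1, ...) {
  m <- object$frames[[frame]]
  df <- expand.grid(x = 0:(ncol(m) - 1), y = 0:(nrow(m) - 1))
  df$intensity <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
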