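#' @importFrom ggplot2 ggplot aes geom_point geom_raster geom_tile geom_hline
#'   geom_rect geom_line scale_fill_viridis_c scale_y_reverse coord_equal
#'   labs theme_minimal annotate
NULL

#' Plot a point pattern
#'
#' @param object An `ens_pattern`.
#' @param colour Optional column name to colour by (e.g. `"class"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ens_pattern <- function(object, colour = NULL, ...) {
  w <- pattern_window(object)
  p <- ggplot(object, aes(x = .data$x, y = .data$y))
  p <- if (!is.null(colour) && colour %in% names(object))
    p + geom_point(aes(colour = .data[[colour]]), size = 1)
  else p + geom_point(size = 1)
  p + coord_equal(xlim = c(0, w[1]), ylim = c(0, w[2])) +
    labs(x = "circumferential x (μm)", y = "longitudinal y (μm)") +
    theme_minimal()
}

#' Plot a CIF map
#'
#' @param object An `ens_cif`.
#' @param which `"smoothed"` (default), `"corrected"` or `"raw"`.
#' @param ... Unused.
#' @return A ggplot of neighbour density over lag space.
#' @export
autoplot.ens_cif <- function(object, which = "smoothed", ...) {
  m <- object[[which]]
  df <- tibble(dx = rep(object$lags, times = length(object$lags)),
               dy = rep(object$lags, each = length(object$lags)),
               value = as.vector(m))
  ggplot(df, aes(x = .data$dx, y = .data$dy, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "neighbour\ndensity") +
    coord_equal() +
    labs(x = "Δx (μm)", y = "Δy (μm)") +
    theme_minimal()
}

#' Plot a z-score result
#'
#' Shows the data's z-score difference against the null band (the random
#' value range).
#'
#' @param object An `ens_zscore`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ens_zscore <- function(object, ...) {
  ggplot() +
    annotate("rect", xmin = 0.6, xmax = 1.4,
             ymin = object$band[1], ymax = object$band[2],
             fill = "grey80") +
    annotate("point", x = 1, y = object$z_diff, size = 3) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = NULL, y = "z-score difference") +
    ggplot2::scale_x_continuous(breaks = NULL, limits = c(0, 2)) +
    theme_minimal()
}

#' Plot a spatiotemporal map
#'
#' Kymograph with time running down the page and position across, darker
#' grey meaning smaller diameter (stronger contraction).
#'
#' @param object An `ens_stm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ens_stm <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$position / 1000, y = .data$time,
                 fill = .data$diameter)) +
    geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey20", high = "grey95",
                                 name = "diameter (μm)") +
    scale_y_reverse() +
    labs(x = "position (mm)", y = "time (s)",
         title = paste("STM,", object$condition)) +
    theme_minimal()
}
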