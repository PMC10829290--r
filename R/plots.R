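#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: an echogram section for a `ping_set`, the UD surface with
#' isopleth outlines for a `ud_surface`, the empirical points and fitted
#' curve for a `variogram_fit`, and dwell-time bars for TAD/TAT
#' histograms.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name preyscape_plots
NULL

#' @rdname preyscape_plots
#' @export
autoplot.ping_set <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$sv_db))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ping, y = .data$depth,
                                   fill = .data$sv_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Sv (dB)") +
    ggplot2::labs(x = "Ping", y = "Depth (m)")
}

#' @rdname preyscape_plots
#' @export
autoplot.ud_surface <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "UD") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)")
  rings <- purrr::imap_dfr(object$polygons, function(pl, lev) {
    purrr::imap_dfr(pl, function(r, i) {
      tibble::tibble(x = r$x, y = r$y, ring = paste(lev, i), level = lev)
    })
  })
  if (nrow(rings) > 0) {
    p <- p + ggplot2::geom_path(
      data = rings,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$ring,
                   colour = .data$level),
      inherit.aes = FALSE
    )
  }
  p
}

#' @rdname preyscape_plots
#' @export
autoplot.variogram_fit <- function(object, ...) {
  ggplot2::ggplot(object$empirical,
                  ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::geom_line(data = object$fitted, colour = "red") +
    ggplot2::geom_vline(xintercept = object$effective_range_m,
                        linetype = "dashed") +
    ggplot2::labs(x = "Lag (m)", y = "Semivariance",
                  size = "Pairs")
}

#' @rdname preyscape_plots
#' @export
autoplot.tad_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin + 0.5,
                                       y = .data$fraction)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_flip() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Depth (m)", y = "Fraction of time")
}

#' @rdname preyscape_plots
#' @export
autoplot.tat_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin + 0.5,
                                       y = .data$fraction)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "Temperature (°C)", y = "Fraction of time")
}
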