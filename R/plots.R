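#' Parity plot of predicted vs observed property values
#'
#' @param predicted,observed Numeric vectors in label units.
#' @param property Property name (controls axis labels and log scaling for
#'   viscosity).
#' @param set Optional grouping vector (e.g. train/validation/test).
#' @return A ggplot.
#' @export
plot_parity <- function(predicted, observed, property = des_properties,
                        set = NULL) {
  property <- match.arg(property)
  df <- tibble::tibble(observed = observed, predicted = predicted,
                       set = set %||% "data")
  unit <- switch(property, density = "g/mL", viscosity = "cP",
                 melting_temperature = "K")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                        colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = sprintf("observed %s (%s)", property, unit),
                  y = sprintf("predicted %s (%s)", property, unit)) +
    ggplot2::theme_minimal()
  if (property == "viscosity") {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' @export
autoplot.des_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$density, .data$viscosity,
                                   colour = .data$melting_temperature)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(name = "Tm (K)") +
    ggplot2::labs(x = "predicted density (g/mL)",
                  y = "predicted viscosity (cP)") +
    ggplot2::theme_minimal()
}

#' Property surface over the 2-D chemical-space map
#'
#' @param surface Output of [export_surface()].
#' @param name Legend title.
#' @return A ggplot.
#' @export
plot_chemspace <- function(surface, name = "value") {
  ggplot2::ggplot(surface$grid, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = surface$points, colour = "grey30",
                        shape = 1, size = 0.8) +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
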