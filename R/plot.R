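#' Plot an unwrapped ocular surface field
#'
#' Equirectangular heat map of the interpolated field magnitude over the
#' eye surface, with the region boundaries drawn and, optionally, the
#' in-region maximum (circle) and the maximum outside the region (star)
#' marked — the montage evaluation at a glance.
#'
#' @param object an `ocular_grid`.
#' @param report optional one-row [locality_report()] tibble whose maxima
#'   are marked.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ocular_grid <- function(object, report = NULL, ...) {
  df <- tidy(object)
  regs <- partition_regions(object$eye %||% "right")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$longitude, y = .data$latitude)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::scale_fill_viridis_c(name = "|E| (V/m)") +
    ggplot2::geom_vline(xintercept = c(regs$lon_min, pi), linetype = "dashed",
                        colour = "white", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "white", linewidth = 0.3) +
    ggplot2::labs(
      x = "longitude (rad)", y = "latitude (rad)",
      title = sprintf("%s eye surface field", object$eye %||% ""),
      subtitle = "dashed: temporal/central/nasal bands and the horizontal meridian"
    ) +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
  if (!is.null(report)) {
    p <- p +
      ggplot2::annotate("point", x = report$lon_in, y = report$lat_in,
                        shape = 21, size = 4, colour = "black", stroke = 1.2) +
      ggplot2::annotate("point", x = report$lon_adjacent, y = report$lat_adjacent,
                        shape = 8, size = 4, colour = "red")
  }
  p
}

#' Plot the locality metrics of a phase comparison
#'
#' Bar chart of the in-region, upper and adjacent maxima per phase and
#' target region.
#'
#' @param object a `phase_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phase_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$reports[, c("phase", "eye", "region", "max_in", "max_upper",
                       "max_adjacent")],
    cols = c("max_in", "max_upper", "max_adjacent"),
    names_to = "zone", values_to = "magnitude"
  )
  df$zone <- factor(df$zone, levels = c("max_in", "max_upper", "max_adjacent"),
                    labels = c("target", "upper", "adjacent"))
  ggplot2::ggplot(df, ggplot2::aes(x = interaction(.data$eye, .data$region, sep = " "),
                                   y = .data$magnitude, fill = .data$zone)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "target region", y = "max |E| (V/m)",
                  title = sprintf("Montage %s: field maxima by zone and phase",
                                  object$montage),
                  fill = NULL) +
    ggplot2::theme_minimal()
}
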