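# Quick-look ggplot2 methods for the package's result types.

#' Plot an energy spectrum
#'
#' Step histogram of fluence per incident proton versus energy.
#'
#' @param object An [energy_spectrum()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.energy_spectrum <- function(object, ...) {
  df <- tibble(energy_mev = c(object$bin_low, max(object$bin_high)),
               fluence = c(object$fluence, object$fluence[nrow(object)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$energy_mev, .data$fluence)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Energy (MeV)",
      y = "Fluence (per incident proton per bin)",
      title = sprintf("%s spectrum", attr(object, "particle"))
    )
}

#' Plot an SOBP depth-dose curve
#'
#' @param object A [build_sobp()] beam.
#' @param ... Ignored.
#' @return A ggplot of the summed depth dose with the flat window marked.
#' @export
autoplot.sobp_beam <- function(object, ...) {
  dd <- attr(object, "depth_dose")
  fw <- attr(object, "flat_window")
  ggplot2::ggplot(dd, ggplot2::aes(.data$depth_cm, .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = fw[1], xmax = fw[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.1) +
    ggplot2::labs(x = "Depth (cm)", y = "Dose (arb. units/proton)",
                  title = sprintf("SOBP, flatness %.2f%%",
                                  100 * attr(object, "flatness")))
}

#' Plot neutron group fluxes by region
#'
#' @param object A `neutron_flux_table` from [thermalize_and_capture()].
#' @param ... Ignored.
#' @return A ggplot on log-log axes.
#' @export
autoplot.neutron_flux_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(sqrt(.data$e_low_ev * .data$e_high_ev),
                               .data$flux, colour = .data$region)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Neutron energy (eV)", y = "Group flux (per proton)",
                  colour = "Region")
}

#' Plot a strand-break yield table
#'
#' @param object A [damage_yield_table()].
#' @param ... Ignored.
#' @return A ggplot of SSB and DSB yields versus alpha energy.
#' @export
autoplot.damage_yield_table <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"energy_mev",
                            names_to = "kind", values_to = "yield")
  ggplot2::ggplot(df, ggplot2::aes(.data$energy_mev, .data$yield,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Alpha energy (MeV)", y = "Strand breaks per alpha",
                  colour = NULL)
}
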