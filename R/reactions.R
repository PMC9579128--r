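# Reaction channels: the two alpha-producing proton captures and the two
# thermal-neutron absorbers. Cross-sections are plateau values above a
# kinematic threshold; the constructor also accepts a tabulated sigma(E).

#' Define a reaction channel
#'
#' @param id Short channel identifier.
#' @param projectile `"p"` or `"n"`.
#' @param target_nuclide Nuclide id, e.g. `"C12"` (its element symbol is
#'   derived for number-density lookups).
#' @param products Character vector of product particle ids.
#' @param sigma_barn Plateau cross-section in barns, or a two-column
#'   data frame (`energy_mev`, `sigma_barn`) for a tabulated channel.
#' @param alpha_multiplicity Number of alpha particles among the products.
#' @param q_value_mev Reaction Q-value in MeV.
#' @param threshold_mev Kinematic threshold for the projectile lab energy.
#'   Defaults to `-Q * (m_proj + m_target) / m_target` for endothermic
#'   channels and 0 otherwise.
#' @return A list of class `reaction_channel`.
#' @export
reaction_channel <- function(id, projectile, target_nuclide, products,
                             sigma_barn, alpha_multiplicity, q_value_mev,
                             threshold_mev = NULL) {
  if (is.data.frame(sigma_barn)) {
    stopifnot(all(c("energy_mev", "sigma_barn") %in% names(sigma_barn)))
    if (any(sigma_barn$sigma_barn < 0)) abort("sigma(E) must be >= 0.")
  } else if (!is.numeric(sigma_barn) || sigma_barn < 0) {
    abort("`sigma_barn` must be a non-negative scalar or a sigma(E) table.")
  }
  n_alpha <- sum(products == "alpha")
  if (alpha_multiplicity != n_alpha) {
    abort(sprintf(
      "alpha_multiplicity (%d) inconsistent with products (%d alphas).",
      alpha_multiplicity, n_alpha
    ))
  }
  if (is.null(threshold_mev)) {
    if (q_value_mev < 0) {
      m_p <- .nuclide_masses[[projectile]]
      m_t <- .nuclide_masses[[target_nuclide]]
      threshold_mev <- -q_value_mev * (m_p + m_t) / m_t
    } else {
      threshold_mev <- 0
    }
  }
  structure(
    list(
      id = id, projectile = projectile, target_nuclide = target_nuclide,
      target_element = gsub("[0-9]", "", target_nuclide),
      products = products, sigma_barn = sigma_barn,
      alpha_multiplicity = alpha_multiplicity,
      q_value_mev = q_value_mev, threshold_mev = threshold_mev
    ),
    class = "reaction_channel"
  )
}

#' @export
print.reaction_channel <- function(x, ...) {
  sig <- if (is.data.frame(x$sigma_barn)) "tabulated" else
    sprintf("%g b", x$sigma_barn)
  cat(sprintf("<reaction_channel %s: %s + %s -> %s (%s, Q = %g MeV)>\n",
              x$id, x$projectile, x$target_nuclide,
              paste(x$products, collapse = " + "), sig, x$q_value_mev))
  invisible(x)
}

#' Channel cross-section at a given projectile energy
#'
#' Plateau channels return the plateau above threshold and 0 below;
#' tabulated channels are linearly interpolated (0 outside the table).
#'
#' @param channel A `reaction_channel`.
#' @param energy_mev Projectile lab kinetic energy (MeV), vectorised.
#' @return Cross-section(s) in barns.
#' @export
channel_sigma <- function(channel, energy_mev) {
  if (is.data.frame(channel$sigma_barn)) {
    approx(channel$sigma_barn$energy_mev, channel$sigma_barn$sigma_barn,
           xout = energy_mev, rule = 1, yleft = 0, yright = 0)$y
  } else {
    ifelse(energy_mev >= channel$threshold_mev, channel$sigma_barn, 0)
  }
}

#' Built-in reaction channels
#'
#' The four channels of the study: 12C(p,3a)p at 400 mb, 19F(p,a)16O at
#' 500 mb, the 157Gd(n,g)158Gd thermal capture at 250000 b and the 10B
#' thermal capture at 4000 b used for comparison. Q-values for the two
#' proton channels are standard nuclear-data constants and can be
#' overridden via [reaction_channel()].
#'
#' Note: the fluorine channel is sometimes written "p + 9F" in the
#' literature this package follows; 19F is the only stable fluorine
#' isotope and is what is meant.
#'
#' @return A named list of `reaction_channel` objects.
#' @export
#' @examples
#' builtin_channels()$C12_p_3alpha
builtin_channels <- function() {
  if (is.null(the$channels)) the$channels <- read_reaction_channels()
  the$channels
}
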