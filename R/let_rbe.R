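# Tabulated LET(E) for alpha particles in tissue and RBE(LET) at 10%
# surviving fraction, with the interpolation/clamping contract used by the
# dose integrator.

#' The alpha-particle LET and RBE lookup table
#'
#' Tabulated linear energy transfer (keV/um) of alpha particles in soft
#' tissue on a 1-12 MeV grid, and the relative biological effectiveness at
#' 10% surviving fraction as a function of that LET. Shipped as a delimited
#' text fixture in `inst/extdata`; LET is strictly decreasing over the grid.
#'
#' @param path Optional path to an alternative three-column table
#'   (`energy_mev`, `let_kev_um`, `rbe`).
#' @return A tibble of class `let_rbe_table`.
#' @export
#' @examples
#' let_rbe_table()
let_rbe_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$let_rbe)) return(the$let_rbe)
    path <- system.file("extdata", "let_rbe_table.tsv", package = "nanodosim",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- as_tibble(read.delim(path))
  validate_let_rbe(tab)
  tab <- structure(tab, class = c("let_rbe_table", class(tab)))
  if (cache) the$let_rbe <- tab
  tab
}

validate_let_rbe <- function(tab) {
  stopifnot(all(c("energy_mev", "let_kev_um", "rbe") %in% names(tab)))
  if (any(tab$let_kev_um <= 0) || any(tab$rbe <= 0)) {
    abort("LET and RBE values must be positive.")
  }
  if (any(diff(tab$let_kev_um) >= 0)) {
    abort("LET must be strictly decreasing in energy over the table grid.")
  }
  invisible(tab)
}

#' LET of an alpha particle
#'
#' Linear interpolation between the tabulated grid points; exact at the
#' grid points. Energies below/above the table are clamped to the end
#' values with a warning (emitted once per call), since realistic alpha
#' spectra extend outside the 1-12 MeV grid.
#'
#' @param energy_mev Alpha kinetic energy in MeV (vectorised, > 0).
#' @param table A [let_rbe_table()].
#' @param warn_clamp Emit a warning when clamping? Default `TRUE`.
#' @return LET in keV/um.
#' @export
#' @examples
#' let_of_energy(c(1, 1.5, 12))
let_of_energy <- function(energy_mev, table = let_rbe_table(),
                          warn_clamp = TRUE) {
  if (any(!is.finite(energy_mev)) || any(energy_mev <= 0)) {
    abort("`energy_mev` must be positive and finite.")
  }
  rng <- range(table$energy_mev)
  clamped <- energy_mev < rng[1] | energy_mev > rng[2]
  if (warn_clamp && any(clamped)) {
    warn(sprintf(
      "%d energie(s) outside the LET table [%g, %g] MeV were clamped.",
      sum(clamped), rng[1], rng[2]
    ))
  }
  e <- pmin(pmax(energy_mev, rng[1]), rng[2])
  approx(table$energy_mev, table$let_kev_um, xout = e)$y
}

#' RBE as a function of LET
#'
#' Linear interpolation of the tabulated RBE(LET) relationship at 10%
#' surviving fraction. LET values outside the tabulated range are
#' clamped with a warning. Exposed for reporting; the dose and damage
#' metrics themselves are not RBE-weighted.
#'
#' @param let_kev_um LET in keV/um (vectorised).
#' @inheritParams let_of_energy
#' @return Dimensionless RBE.
#' @export
#' @examples
#' rbe_of_let(c(200, 130, 53))
rbe_of_let <- function(let_kev_um, table = let_rbe_table(),
                       warn_clamp = TRUE) {
  if (any(!is.finite(let_kev_um)) || any(let_kev_um <= 0)) {
    abort("`let_kev_um` must be positive and finite.")
  }
  ord <- order(table$let_kev_um)
  rng <- range(table$let_kev_um)
  clamped <- let_kev_um < rng[1] | let_kev_um > rng[2]
  if (warn_clamp && any(clamped)) {
    warn(sprintf(
      "%d LET value(s) outside the RBE table [%g, %g] keV/um were clamped.",
      sum(clamped), rng[1], rng[2]
    ))
  }
  l <- pmin(pmax(let_kev_um, rng[1]), rng[2])
  approx(table$let_kev_um[ord], table$rbe[ord], xout = l)$y
}
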