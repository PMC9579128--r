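# Physical constants and nuclide data used across the package.

#' Physical constants
#'
#' Avogadro's number, the barn in cm^2, and the keV/um-to-Gy conversion
#' constant used in the fluence-weighted dose sum.
#'
#' @format A named list with elements `avogadro` (1/mol), `barn_cm2` (cm^2),
#'   and `kev_um_to_gy` (the conversion constant 1.6e-13 applied to
#'   fluence x LET sums).
#' @export
nd_constants <- list(
  avogadro     = 6.02214076e23,
  barn_cm2     = 1e-24,
  kev_um_to_gy = 1.6e-13
)

# Atomic masses in g/mol. Gd is the 157 isotope (157 g/mol by convention in
# the Gd neutron-capture literature); B is the 10 isotope.
.atomic_masses <- c(
  H = 1.008, B = 10.013, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Li = 7.016, Gd = 157.0
)

# Nuclide masses (amu) for reaction kinematics.
.nuclide_masses <- c(
  p = 1.007825, n = 1.008665, alpha = 4.002602,
  C12 = 12.0, O16 = 15.994915, F19 = 18.998403,
  Gd157 = 156.923968, Gd158 = 157.924112, B10 = 10.012937, Li7 = 7.016004,
  gamma = 0
)

#' Look up an atomic mass
#'
#' @param element Character vector of element symbols (e.g. `"C"`, `"Gd"`).
#' @return Atomic masses in g/mol.
#' @export
#' @examples
#' atomic_mass(c("H", "C", "Gd"))
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    abort(paste0(
      "Unknown element symbol(s): ",
      paste(element[is.na(m)], collapse = ", ")
    ))
  }
  unname(m)
}
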