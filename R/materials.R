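# Materials: name + mass density + elemental mass fractions, with the
# number-density arithmetic that turns cross-sections in barns into
# macroscopic interaction coefficients.

#' Define a material
#'
#' A material is a tibble of elemental mass fractions carrying its name and
#' mass density as attributes. Mass fractions must close to 1 within 1e-9.
#'
#' @param name Material name.
#' @param density_g_cm3 Mass density in g/cm^3 (> 0).
#' @param composition Named numeric vector of elemental mass fractions,
#'   e.g. `c(H = 0.10, O = 0.70, C = 0.20)`.
#' @return A tibble of class `nd_material` with columns `element` and
#'   `mass_fraction`.
#' @export
#' @examples
#' material("water", 1.0, c(H = 0.112, O = 0.888))
material <- function(name, density_g_cm3, composition) {
  if (!is.numeric(density_g_cm3) || length(density_g_cm3) != 1 ||
      density_g_cm3 <= 0) {
    abort("`density_g_cm3` must be a single positive number.")
  }
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    abort("`composition` must be a named numeric vector of mass fractions.")
  }
  if (any(composition < 0)) abort("Mass fractions must be non-negative.")
  if (abs(sum(composition) - 1) > 1e-9) {
    abort(sprintf(
      "Mass fractions of '%s' sum to %.12f, not 1 (tolerance 1e-9).",
      name, sum(composition)
    ))
  }
  atomic_mass(names(composition)) # errors early on unknown symbols
  out <- tibble(element = names(composition),
                mass_fraction = unname(composition))
  structure(out, name = name, density_g_cm3 = density_g_cm3,
            class = c("nd_material", class(out)))
}

#' @export
print.nd_material <- function(x, ...) {
  cat(sprintf("<material: %s, %.3g g/cm3>\n",
              attr(x, "name"), attr(x, "density_g_cm3")))
  NextMethod()
}

#' Built-in materials
#'
#' The three materials of the nano-target study: soft tissue
#' (H 10%, O 70%, C 20%, 1.1 g/cm3), the carbon nano-target (2.2 g/cm3) and
#' the GdF4 nano-target (Gd 68%, F 32%, 7.1 g/cm3; the Gd is the 157 isotope).
#'
#' @return An `nd_material`.
#' @export
tissue_material <- function() shipped_materials()$tissue

#' @rdname tissue_material
#' @export
carbon_material <- function() shipped_materials()$carbon

#' @rdname tissue_material
#' @export
gdf4_material <- function() shipped_materials()$GdF4

#' Dope a material with gadolinium-157
#'
#' Adds `ppm` (parts per million by mass) of 157Gd to a material, rescaling
#' the host fractions so the composition still closes to 1. The density is
#' left unchanged (dilute-dopant approximation).
#'
#' @param mat An `nd_material`.
#' @param ppm Gd mass concentration in ppm (>= 0).
#' @return A doped `nd_material`.
#' @export
#' @examples
#' with_gd(tissue_material(), 3000)
with_gd <- function(mat, ppm) {
  stopifnot(inherits(mat, "nd_material"))
  if (!is.numeric(ppm) || length(ppm) != 1 || ppm < 0) {
    abort("`ppm` must be a single non-negative number.")
  }
  if (ppm == 0) return(mat)
  f <- ppm * 1e-6
  comp <- setNames(mat$mass_fraction * (1 - f), mat$element)
  if ("Gd" %in% names(comp)) {
    comp[["Gd"]] <- comp[["Gd"]] + f
  } else {
    comp <- c(comp, Gd = f)
  }
  material(paste0(attr(mat, "name"), sprintf("+Gd(%gppm)", ppm)),
           attr(mat, "density_g_cm3"), comp)
}

#' Elemental number densities of a material
#'
#' n_i = rho * w_i / A_i * N_A, in atoms/cm^3.
#'
#' @param mat An `nd_material`.
#' @return A tibble with columns `element`, `mass_fraction`,
#'   `atomic_mass_g_mol`, `n_cm3`.
#' @export
#' @examples
#' number_densities(carbon_material()) # n_C ~ 1.10e23 cm^-3
number_densities <- function(mat) {
  stopifnot(inherits(mat, "nd_material"))
  rho <- attr(mat, "density_g_cm3")
  tibble(
    element = mat$element,
    mass_fraction = mat$mass_fraction,
    atomic_mass_g_mol = atomic_mass(mat$element),
    n_cm3 = rho * mat$mass_fraction / atomic_mass(mat$element) *
      nd_constants$avogadro
  )
}

#' Macroscopic cross-section
#'
#' Sigma = n * sigma * 1e-24, in 1/cm. Vectorised and linear in both
#' arguments.
#'
#' @param n_cm3 Number density in atoms/cm^3 (>= 0).
#' @param sigma_barn Microscopic cross-section in barns (>= 0).
#' @return Macroscopic cross-section(s) in 1/cm.
#' @export
#' @examples
#' macroscopic_sigma(1.27e19, 250000) # ~3.2 /cm: 3000 ppm 157Gd in tissue
macroscopic_sigma <- function(n_cm3, sigma_barn) {
  if (any(n_cm3 < 0) || any(sigma_barn < 0)) {
    abort("`n_cm3` and `sigma_barn` must be non-negative.")
  }
  n_cm3 * sigma_barn * nd_constants$barn_cm2
}

# number density of one element in a material (0 if absent)
element_density <- function(mat, element) {
  nd <- number_densities(mat)
  i <- match(element, nd$element)
  if (is.na(i)) 0 else nd$n_cm3[i]
}
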