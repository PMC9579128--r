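# SOBP clinical beam: power-law range-energy model, analytic pristine
# Bragg curves with Gaussian range straggling, NNLS-weighted spread-out
# peak, and the sampled in-tumor proton energy spectrum.

# Default range-energy coefficients for R = alpha * E^p in tissue.
# p = 1.77 is the standard proton power-law exponent in this energy range;
# alpha is set so a 60 MeV proton retains 32 MeV at 2 cm depth (the upper
# end of the in-tumor spectrum), which also puts the 50 and 60 MeV Bragg
# positions at 2.16 and 2.98 cm.
range_coefficients <- function() {
  p <- 1.77
  list(p = p, alpha = 2 / (60^p - 32^p))
}

#' Proton CSDA range
#'
#' Power-law range-energy relation `R = alpha * E^p` in the given material
#' (density-scaled relative to tissue). Strictly increasing in energy.
#'
#' @param energy_mev Proton kinetic energy in MeV (0 < E <= 250), vectorised.
#' @param material An `nd_material`; default tissue.
#' @param coef Range-model coefficients (override via a list with `alpha`
#'   and `p`).
#' @return Range(s) in cm.
#' @export
#' @examples
#' csda_range(c(50, 60)) # ~2.2, ~3.0 cm in tissue
csda_range <- function(energy_mev, material = tissue_material(),
                       coef = range_coefficients()) {
  if (any(energy_mev <= 0) || any(energy_mev > 250)) {
    abort("`energy_mev` must be in (0, 250].")
  }
  scale <- 1.1 / attr(material, "density_g_cm3")
  scale * coef$alpha * energy_mev^coef$p
}

#' Proton energy with a given residual range
#'
#' Inverse of [csda_range()]; returns 0 for non-positive residual range.
#'
#' @param range_cm Residual range in cm, vectorised.
#' @inheritParams csda_range
#' @return Energy in MeV.
#' @export
energy_at_range <- function(range_cm, material = tissue_material(),
                            coef = range_coefficients()) {
  scale <- 1.1 / attr(material, "density_g_cm3")
  (pmax(range_cm, 0) / (scale * coef$alpha))^(1 / coef$p)
}

# Pristine bin-integrated depth-dose of one mono-energetic component,
# blurred by Gaussian range straggling (sigma_r = p * sigma_e_frac * R).
pristine_depth_dose <- function(energy_mev, depth_edges,
                                material = tissue_material(),
                                sigma_e_frac = 0.02,
                                coef = range_coefficients()) {
  R <- csda_range(energy_mev, material, coef)
  sig_r <- coef$p * sigma_e_frac * R
  dep <- energy_at_range(R - head(depth_edges, -1), material, coef) -
    energy_at_range(R - tail(depth_edges, -1), material, coef)
  h <- diff(depth_edges)[1]
  kz <- seq(-4 * sig_r, 4 * sig_r, by = h)
  k <- dnorm(kz, sd = sig_r)
  k <- k / sum(k)
  pad <- length(k)
  sm <- as.numeric(stats::filter(c(rep(0, pad), dep, rep(0, pad)), k,
                                 sides = 2))
  sm[(pad + 1):(pad + length(dep))] / h
}

#' Build a spread-out Bragg peak
#'
#' Places `n_peaks` mono-energetic components with Bragg positions spanning
#' the intersection of the requested depth window with the reach of the
#' allowed beam energies, and solves a non-negative least-squares problem
#' for the component weights that flatten the summed depth-dose. Flatness
#' is evaluated over the covered window minus one range-straggling sigma at
#' the distal end (the distal falloff is physical and cannot be flattened).
#'
#' @param depth_window Numeric length-2, the tumor depth window in cm
#'   (default `c(2, 3)`).
#' @param n_peaks Number of pristine peaks (>= 1, default 11).
#' @param material Stopping material, default tissue.
#' @param energy_range_mev Allowed beam energies in MeV, default
#'   `c(50, 60)`.
#' @param sigma_e_frac Fractional Gaussian energy straggling (default 0.02).
#' @param flatness_tol Maximum allowed `max/min - 1` of the depth dose over
#'   the flat region (default 0.05); exceeding it is an error.
#' @return A tibble of class `sobp_beam` with columns `peak_energy_mev`,
#'   `peak_range_cm`, `weight` (normalised to 1), and attributes
#'   `depth_window`, `flat_window`, `flatness`, `depth_dose` (a tibble
#'   `depth_cm`, `dose`), `material`, `sigma_e_frac`.
#' @export
#' @examples
#' beam <- build_sobp(n_peaks = 5)
#' attr(beam, "flatness")
build_sobp <- function(depth_window = c(2, 3), n_peaks = 11,
                       material = tissue_material(),
                       energy_range_mev = c(50, 60),
                       sigma_e_frac = 0.02, flatness_tol = 0.05) {
  if (n_peaks < 1) abort("`n_peaks` must be >= 1.")
  coef <- range_coefficients()
  reach <- csda_range(energy_range_mev, material, coef)
  covered <- c(max(depth_window[1], reach[1]), min(depth_window[2], reach[2]))
  if (covered[1] >= covered[2] && n_peaks > 1) {
    abort(sprintf(
      "Depth window [%g, %g] cm is not reachable with beam energies [%g, %g] MeV (reach [%.2f, %.2f] cm).",
      depth_window[1], depth_window[2], energy_range_mev[1],
      energy_range_mev[2], reach[1], reach[2]
    ))
  }
  if (n_peaks == 1) {
    peak_ranges <- covered[2]
  } else {
    peak_ranges <- seq(covered[1], covered[2], length.out = n_peaks)
  }
  energies <- energy_at_range(peak_ranges, material, coef)

  edges <- seq(0, max(reach) * 1.15, by = 0.004)
  mids <- head(edges, -1) + diff(edges) / 2
  D <- vapply(energies, function(e) {
    pristine_depth_dose(e, edges, material, sigma_e_frac, coef)
  }, numeric(length(mids)))
  D <- matrix(D, ncol = n_peaks)

  sig_r <- coef$p * sigma_e_frac * covered[2]
  flat_window <- c(covered[1], covered[2] - sig_r)
  if (n_peaks == 1) {
    w <- 1
    flat_window <- c(covered[2] - sig_r, covered[2] - sig_r)
  } else {
    sel <- mids >= flat_window[1] & mids <= flat_window[2]
    fit <- pracma::lsqnonneg(D[sel, , drop = FALSE], rep(1, sum(sel)))
    w <- fit$x / sum(fit$x)
  }
  dose <- as.numeric(D %*% w)
  sel <- mids >= flat_window[1] & mids <= flat_window[2]
  flatness <- if (any(sel)) max(dose[sel]) / min(dose[sel]) - 1 else 0
  if (n_peaks > 1 && flatness > flatness_tol) {
    abort(sprintf(
      "SOBP flatness %.3f exceeds tolerance %.3f; increase n_peaks.",
      flatness, flatness_tol
    ))
  }
  out <- tibble(peak_energy_mev = energies, peak_range_cm = peak_ranges,
                weight = w)
  structure(out,
            depth_window = depth_window, flat_window = flat_window,
            flatness = flatness,
            depth_dose = tibble(depth_cm = mids, dose = dose),
            material = material, sigma_e_frac = sigma_e_frac,
            class = c("sobp_beam", class(out)))
}

#' Depth-dose curve of an SOBP beam
#'
#' The weighted superposition of the pristine component curves, evaluated
#' at arbitrary depths by interpolating the stored fine-grid curve.
#'
#' @param beam A [build_sobp()] result.
#' @param depth_cm Depths in cm.
#' @return A tibble `depth_cm`, `dose` (arbitrary units per proton).
#' @export
depth_dose <- function(beam, depth_cm) {
  stopifnot(inherits(beam, "sobp_beam"))
  dd <- attr(beam, "depth_dose")
  tibble(depth_cm = depth_cm,
         dose = approx(dd$depth_cm, dd$dose, xout = depth_cm, rule = 2)$y)
}

#' Sampled proton energy spectrum inside the tumor
#'
#' Samples protons from the SOBP components (by weight), a depth uniform in
#' the tumor window, and converts residual range to residual energy with
#' Gaussian energy straggling. Protons whose range ends short of the
#' sampled depth are scored as stopped (first bin). The spectrum is
#' histogrammed in 1 MeV bins over 0-33 MeV; its support is bounded by the
#' residual energy of the most energetic component at the proximal face
#' (32 MeV for the default beam).
#'
#' @param beam A [build_sobp()] result.
#' @param depth_window Depth window to sample in cm; defaults to the beam's.
#' @param n_protons Number of sampled protons (default 1e5).
#' @param seed Integer seed (sampling is fully reproducible).
#' @return An [energy_spectrum()] of protons.
#' @export
in_tumor_proton_spectrum <- function(beam, depth_window = NULL,
                                     n_protons = 1e5, seed = 1L) {
  stopifnot(inherits(beam, "sobp_beam"))
  if (n_protons < 1) abort("`n_protons` must be >= 1.")
  if (is.null(depth_window)) depth_window <- attr(beam, "depth_window")
  if (length(depth_window) != 2 || depth_window[2] < depth_window[1]) {
    abort("`depth_window` must be c(low, high) with high >= low.")
  }
  material <- attr(beam, "material")
  sigma_e <- attr(beam, "sigma_e_frac")
  coef <- range_coefficients()

  withr_seed(seed, {
    comp <- sample.int(nrow(beam), n_protons, replace = TRUE,
                       prob = beam$weight)
    d <- runif(n_protons, depth_window[1], depth_window[2])
    res_range <- beam$peak_range_cm[comp] - d
    e <- energy_at_range(res_range, material, coef)
    e <- e * (1 + sigma_e * rnorm(n_protons))
    e_max <- energy_at_range(max(beam$peak_range_cm) - depth_window[1],
                             material, coef)
    e <- pmin(pmax(e, 0), e_max)
  })

  edges <- proton_bin_edges()
  h <- bin_fluence(e, rep(1 / n_protons, n_protons), edges)
  energy_spectrum(edges, h$fluence, "proton", counts = h$count,
                  n_protons = n_protons, seed = seed)
}

# evaluate `code` under a local RNG seed, restoring the global state;
# assigns into the caller frame
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval(substitute(code), envir = parent.frame())
}
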