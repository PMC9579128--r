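test_that("the evaporation source is seeded, linear in yield, and has mean 2T", {
  s1 <- neutron_source(n_events = 5e3, seed = 8)
  s2 <- neutron_source(n_events = 5e3, seed = 8)
  expect_identical(s1$flux_per_proton, s2$flux_per_proton)
  expect_equal(sum(s1$flux_per_proton), 1e-3, tolerance = 1e-9)
  s0 <- neutron_source(n_events = 100, seed = 1, neutrons_per_proton = 0)
  expect_true(all(s0$flux_per_proton == 0))
  s3 <- neutron_source(n_events = 5e3, seed = 8, neutrons_per_proton = 2e-3)
  expect_equal(s3$flux_per_proton, 2 * s1$flux_per_proton)
  # sample mean against the closed-form Maxwellian mean 2T, T = 1 MeV
  t_mev <- 1
  se <- t_mev * sqrt(2) / sqrt(attr(s1, "n_events"))
  expect_lt(abs(attr(s1, "mean_energy_mev") - 2 * t_mev), 3 * se)
})

test_that("a purely absorbing single group attenuates as exp(-Sigma x)", {
  n_target <- 3.2 / (250000 * 1e-24)
  rho <- n_target * 157 / nd_constants$avogadro
  m <- material("gd_absorber_synthetic", rho, c(Gd = 1))
  src <- neutron_source(n_events = 1, seed = 1, neutrons_per_proton = 1,
                        groups = neutron_groups(c(1e-5, 0.5)))
  tr <- layer_transmission(src, m, 1)
  expect_equal(tr$flux_out, exp(-3.2), tolerance = 1e-6)
})

test_that("slowing-down current is conserved when capture is off", {
  src <- rep(1 / 8, 8)
  bal <- nanodosim:::slowing_down_balance(
    c(src[8], rep(0, 7)), sa = rep(0, 8), srem = c(rep(0.5, 7), 0)
  )
  # all source enters the top group; with no absorption the current
  # entering every group equals the source
  expect_lt(max(abs(bal$q_in - bal$q_in[1])), 1e-9)
  expect_equal(sum(bal$absorbed), 0)
})

test_that("Gd-157 out-captures B-10 by exactly the 62.5x cross-section ratio in the thermal group", {
  # equal number densities: B mass fraction scaled by the mass ratio
  f_gd <- 1e-3
  f_b <- f_gd * 10.013 / 157
  host <- tissue_material()
  comp <- setNames(host$mass_fraction * (1 - f_gd - f_b), host$element)
  m <- material("dual_dopant", 1.1, c(comp, Gd = f_gd, B = f_b))
  gx <- nanodosim:::group_cross_sections(m, neutron_groups())
  thermal <- 1 # first row of neutron_groups() is the thermal group
  expect_equal(unname(gx$sa_nuc["Gd", thermal] / gx$sa_nuc["B", thermal]),
               62.5, tolerance = 1e-9)
})

test_that("no gadolinium anywhere reproduces the baseline flux identically", {
  src <- neutron_source(n_events = 2e3, seed = 4)
  f0 <- thermalize_and_capture(src, default_slab(0))
  f0b <- thermalize_and_capture(src, default_slab(0, partition_ratio = 7))
  expect_identical(f0$flux, f0b$flux)
  nf <- generate_neutron_fluxes(seed = 4, gd_ppm = 0, n_events = 2e3)
  expect_identical(nf$with$flux, nf$without$flux)
})

test_that("thermal-to-1 keV band flux is non-increasing in gd_ppm over 0-6000 ppm", {
  src <- neutron_source(n_events = 2e3, seed = 4)
  grid <- c(0, 500, 1500, 3000, 6000)
  bands <- vapply(grid, function(ppm) {
    f <- thermalize_and_capture(src, default_slab(ppm))
    vapply(split(f$flux[f$e_high_ev <= 1e3], f$region[f$e_high_ev <= 1e3]),
           sum, numeric(1))
  }, numeric(2))
  expect_true(all(diff(bands["tumor", ]) < 0))
  expect_true(all(diff(bands["healthy", ]) < 0))
  # and the thermal group itself, in both regions
  thermal <- vapply(grid, function(ppm) {
    f <- thermalize_and_capture(src, default_slab(ppm))
    f$flux[f$e_high_ev <= 0.5]
  }, numeric(2))
  expect_true(all(diff(t(thermal)) < 0))
})

test_that("3000 ppm suppresses the tumor band more strongly than healthy tissue at 70:1", {
  nf <- generate_neutron_fluxes(seed = 1, gd_ppm = 3000, n_events = 2e3)
  rr <- reduction_report(nf$with, nf$without)
  expect_gt(rr$reduction_pct[rr$region == "tumor"],
            rr$reduction_pct[rr$region == "healthy"])
  expect_gt(rr$factor[rr$region == "tumor"], 10)
})

test_that("reduction arithmetic matches the reference fluences", {
  mk <- function(tumor, healthy) {
    structure(
      tibble::tibble(region = c("tumor", "healthy"),
                     e_low_ev = 1e-5, e_high_ev = 0.5,
                     flux = c(tumor, healthy)),
      class = c("neutron_flux_table", class(tibble::tibble()))
    )
  }
  rr <- reduction_report(mk(3.0e-7, 2e-7), mk(2.0e-6, 4e-7))
  expect_equal(rr$reduction_pct[rr$region == "healthy"], 50)
  expect_equal(rr$factor[rr$region == "tumor"], 2.0e-6 / 3.0e-7)
  rr0 <- reduction_report(mk(1, 1), mk(1, 1))
  expect_equal(rr0$reduction_pct, c(0, 0))
  expect_error(reduction_report(mk(1, 1), mk(0, 0)), "zero")
})

test_that("baseline synthetic fluxes are anchored to the reference band fluences", {
  nf <- generate_neutron_fluxes(seed = 2, n_events = 2e3)
  band <- function(x, rg) {
    sum(x$flux[x$region == rg & x$e_high_ev <= 1e3])
  }
  expect_equal(band(nf$without, "tumor"), 2.0e-6, tolerance = 1e-9)
  expect_equal(band(nf$without, "healthy"), 4e-7, tolerance = 1e-9)
})

test_that("slab geometry validates thickness, ppm, and tumor index", {
  expect_error(default_slab(-1), "non-negative")
  lay <- tibble::tibble(name = "a", material = list(tissue_material()),
                        thickness_cm = -1, gd_ppm = 0)
  expect_error(slab_geometry(lay, 1), "> 0")
  lay$thickness_cm <- 1
  expect_error(slab_geometry(lay, 5), "out of range")
})
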