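test_that("shipped materials close to unit mass fraction and carry the published densities", {
  mats <- list(tissue_material(), carbon_material(), gdf4_material())
  for (m in mats) {
    expect_lt(abs(sum(m$mass_fraction) - 1), 1e-9)
    expect_gt(attr(m, "density_g_cm3"), 0)
  }
  expect_equal(attr(tissue_material(), "density_g_cm3"), 1.1)
  expect_equal(attr(carbon_material(), "density_g_cm3"), 2.2)
  expect_equal(attr(gdf4_material(), "density_g_cm3"), 7.1)
  expect_equal(
    setNames(tissue_material()$mass_fraction, tissue_material()$element),
    c(H = 0.10, O = 0.70, C = 0.20)
  )
})

test_that("material constructor rejects bad input and names unknown elements", {
  expect_error(material("x", -1, c(C = 1)), "positive")
  expect_error(material("x", 1, c(C = 0.9)), "sum to")
  expect_error(material("x", 1, c(Xx = 1)), "Xx")
})

test_that("number densities match hand calculations", {
  n_c <- number_densities(carbon_material())$n_cm3
  expect_equal(n_c, 1.10e23, tolerance = 0.01) # 2.2/12.011 * N_A
  nd <- number_densities(gdf4_material())
  expect_equal(nd$n_cm3[nd$element == "Gd"], 1.85e22,
               tolerance = 0.01) # 7.1*0.68/157 * N_A
  # zero-fraction element has zero number density
  m <- material("mix", 1.0, c(H = 1, O = 0))
  expect_equal(number_densities(m)$n_cm3[2], 0)
})

test_that("macroscopic cross-section is Sigma = n sigma 1e-24, linear in both arguments", {
  expect_equal(macroscopic_sigma(0, 100), 0)
  # 3000 ppm (mass) 157Gd in tissue, 250000 b
  n_gd <- number_densities(with_gd(tissue_material(), 3000))
  n <- n_gd$n_cm3[n_gd$element == "Gd"]
  expect_equal(macroscopic_sigma(n, 250000), 3.2, tolerance = 0.02)
  set.seed(42)
  for (i in 1:20) {
    n <- runif(1, 0, 1e24); s <- runif(1, 0, 1e5); a <- runif(1, 0, 10)
    expect_equal(macroscopic_sigma(a * n, s), a * macroscopic_sigma(n, s))
    expect_equal(macroscopic_sigma(n, a * s), a * macroscopic_sigma(n, s))
  }
  expect_error(macroscopic_sigma(-1, 1), "non-negative")
})

test_that("LET lookup is exact at every tabulated grid point and interpolates between", {
  tab <- let_rbe_table()
  expect_equal(let_of_energy(tab$energy_mev), tab$let_kev_um)
  expect_equal(let_of_energy(1), 200)
  expect_equal(let_of_energy(12), 53)
  # independent hand interpolation: midpoint of (1, 200) and (2, 140)
  expect_equal(let_of_energy(1.5), (200 + 140) / 2)
  expect_gt(let_of_energy(1.5), 140)
  expect_lt(let_of_energy(1.5), 200)
  expect_error(let_of_energy(-1), "positive")
  expect_warning(let_of_energy(0.5), "clamped")
  expect_equal(suppressWarnings(let_of_energy(0.5)), 200)
  expect_equal(suppressWarnings(let_of_energy(14)), 53)
})

test_that("RBE lookup reproduces the tabulated RBE(LET) pairs and clamps outside", {
  expect_equal(rbe_of_let(200), 2.4)
  expect_equal(rbe_of_let(130), 4.5)
  expect_equal(rbe_of_let(53), 3)
  expect_warning(rbe_of_let(250), "clamped")
  expect_equal(suppressWarnings(rbe_of_let(250)), 2.4)
})

test_that("reaction channels carry the published cross-sections and consistent multiplicities", {
  ch <- builtin_channels()
  expect_equal(ch$C12_p_3alpha$sigma_barn, 0.400)
  expect_equal(ch$F19_p_alpha$sigma_barn, 0.500)
  expect_equal(ch$Gd157_n_gamma$sigma_barn, 250000)
  expect_equal(ch$B10_n_alpha$sigma_barn, 4000)
  expect_equal(ch$C12_p_3alpha$alpha_multiplicity, 3)
  expect_equal(ch$F19_p_alpha$alpha_multiplicity, 1)
  expect_equal(ch$Gd157_n_gamma$alpha_multiplicity, 0)
  # endothermic threshold: -Q (m_p + m_C) / m_C
  expect_equal(ch$C12_p_3alpha$threshold_mev, 7.275 * 13.007825 / 12,
               tolerance = 1e-6)
  expect_equal(ch$F19_p_alpha$threshold_mev, 0)
  # sub-threshold plateau channels return zero cross-section
  expect_equal(channel_sigma(ch$C12_p_3alpha, 5), 0)
  expect_equal(channel_sigma(ch$C12_p_3alpha, 20), 0.4)
  expect_error(
    reaction_channel("bad", "p", "C12", c("alpha", "p"), 0.1, 3, -7),
    "inconsistent"
  )
})

test_that("doping tissue with Gd preserves mass-fraction closure and scales linearly", {
  m <- with_gd(tissue_material(), 3000)
  expect_lt(abs(sum(m$mass_fraction) - 1), 1e-9)
  expect_equal(m$mass_fraction[m$element == "Gd"], 3e-3)
  n1 <- number_densities(with_gd(tissue_material(), 1000))
  n2 <- number_densities(with_gd(tissue_material(), 2000))
  expect_equal(n2$n_cm3[n2$element == "Gd"] / n1$n_cm3[n1$element == "Gd"],
               2, tolerance = 1e-6)
})
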