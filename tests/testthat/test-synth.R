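test_that("calibration hits every reference target within tolerance", {
  cal <- calibrate_recipe()
  expect_true(all(abs(cal$achieved$rel_error) < 0.02))
  # exactly-determined solves are exact, not just within tolerance
  expect_lt(max(abs(cal$achieved$rel_error)), 1e-9)
})

test_that("calibration is deterministic and idempotent", {
  c1 <- calibrate_recipe()
  c2 <- calibrate_recipe()
  expect_equal(c1$recipe$scales, c2$recipe$scales, tolerance = 1e-12)
  # recalibrating a recipe that already carries fitted scales refits to
  # the identical values
  c3 <- calibrate_recipe(c1$recipe)
  expect_equal(c3$recipe$scales, c1$recipe$scales, tolerance = 1e-12)
})

test_that("calibrating only the no-target dose scale is an exact 1-unknown solve", {
  targets <- reference_targets()
  targets$dose_damage <- targets$dose_damage[
    targets$dose_damage$agent == "none", ]
  cal <- calibrate_recipe(targets = targets)
  ach <- cal$achieved
  expect_equal(
    ach$achieved[ach$quantity == "dose_gy_per_proton"], 7e-9,
    tolerance = 1e-12
  )
})

test_that("the calibrated excess concentrates in the 1-6 MeV band for both agents", {
  recipe <- calibrated_recipe()
  base <- nanodosim:::expected_fluence(recipe, "none")
  ctr <- seq(0.5, 14.5, by = 1)
  for (agent in c("C", "GdF4")) {
    excess <- nanodosim:::expected_fluence(recipe, agent) - base
    expect_true(all(excess > -1e-12))
    expect_gt(sum(excess[ctr > 1 & ctr < 6]) / sum(excess), 0.5)
  }
})

test_that("generated spectra are seed-deterministic with Poisson-level seed sensitivity", {
  s1 <- generate_alpha_spectra(agent = "C", seed = 10)
  s2 <- generate_alpha_spectra(agent = "C", seed = 10)
  expect_identical(s1$fluence, s2$fluence)
  s3 <- generate_alpha_spectra(agent = "C", seed = 11)
  expect_false(identical(s1$fluence, s3$fluence))
  # relative differences between seeds scale as 1/sqrt(counts)
  nz <- s1$count > 1000
  rel <- abs(s1$count[nz] - s3$count[nz]) / s1$count[nz]
  expect_lt(max(rel), 10 / sqrt(min(s1$count[nz])))
})

test_that("unknown agents are rejected by name", {
  recipe <- calibrated_recipe()
  expect_error(nanodosim:::expected_fluence(recipe, "boron"), "boron")
})

test_that("rescaling every spectrum scale leaves enhancements unchanged", {
  recipe <- calibrated_recipe()
  d <- function(fl) {
    total_dose(energy_spectrum(seq(0, 15, 1), fl, "alpha"))$total_gy_per_proton
  }
  base <- nanodosim:::expected_fluence(recipe, "none")
  withc <- nanodosim:::expected_fluence(recipe, "C")
  e1 <- enhancement_percent(d(withc), d(base), rounding = "exact")
  k <- 7.3
  e2 <- enhancement_percent(d(k * withc), d(k * base), rounding = "exact")
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("noise-free generated spectra reproduce the reference dose and damage", {
  recipe <- calibrated_recipe()
  ytab <- calibrate_recipe()$yield_table
  s_none <- generate_alpha_spectra(recipe, "none", noise = FALSE)
  expect_equal(total_dose(s_none)$total_gy_per_proton, 7e-9,
               tolerance = 1e-9)
  s_c <- generate_alpha_spectra(recipe, "C", noise = FALSE)
  sb <- total_strand_breaks(s_c, ytab)
  expect_equal(sb$ssb_per_proton, 4.7e4, tolerance = 1e-9)
})

test_that("the shipped damage-yield fixture regenerates from the calibration solve", {
  shipped <- damage_yield_table()
  refit <- calibrate_recipe()$yield_table
  expect_equal(shipped$energy_mev, refit$energy_mev)
  expect_equal(shipped$ssb_per_alpha, refit$ssb_per_alpha, tolerance = 1e-9)
  expect_equal(shipped$dsb_per_alpha, refit$dsb_per_alpha, tolerance = 1e-9)
})

test_that("an infeasible target set fails loudly", {
  targets <- reference_targets()
  # dose excess impossible to reconcile with a huge SSB excess
  targets$dose_damage$ssb_per_proton[targets$dose_damage$agent == "C"] <- 1e9
  expect_error(calibrate_recipe(targets = targets), "negative|tolerance")
})
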