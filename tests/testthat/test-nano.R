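test_that("thin-target interaction probability matches the hand estimate and is linear in thickness", {
  geo <- nano_geometry()
  ch <- builtin_channels()$C12_p_3alpha
  # n_C(2.2 g/cm3) * 400 mb * 50 nm ~ 2.2e-7 per proton
  expect_equal(interaction_probability(ch, geo, 20), 2.2e-7,
               tolerance = 0.01)
  expect_equal(interaction_probability(ch, geo, 5), 0) # below threshold
  geo2 <- nano_geometry(thickness_nm = 100)
  expect_equal(interaction_probability(ch, geo2, 20),
               2 * interaction_probability(ch, geo, 20))
  geo_f <- nano_geometry(gdf4_material())
  chf <- builtin_channels()$F19_p_alpha
  expect_gt(interaction_probability(chf, geo_f, 1), 0)
  expect_error(nano_geometry(thickness_nm = 0), "> 0")
})

test_that("two-body alpha energies match the textbook lab-frame closed form", {
  ch <- builtin_channels()$F19_p_alpha
  for (ep in c(0.5, 5, 20)) {
    fwd <- two_body_alpha_energy(ep, 1, ch)
    bwd <- two_body_alpha_energy(ep, -1, ch)
    # forward CM emission = forward lab emission (+ root), backward
    # likewise; the two non-relativistic formulations book-keep the 8.7 mamu
    # mass defect differently, so agreement is to ~Q/(m c^2) ~ 5e-4
    expect_equal(fwd, lab_two_body_energy(ep, 1, 1.007825, 4.002602,
                                          15.994915, 8.114),
                 tolerance = 1e-3)
    expect_equal(bwd, lab_two_body_energy(ep, -1, 1.007825, 4.002602,
                                          15.994915, 8.114),
                 tolerance = 1e-3)
    expect_gt(fwd, bwd)
  }
})

test_that("every sampled reaction event conserves energy exactly", {
  chc <- builtin_channels()$C12_p_3alpha
  chf <- builtin_channels()$F19_p_alpha
  set.seed(99)
  ep_c <- runif(1e4, 8, 32)
  ep_f <- runif(1e4, 0.5, 32)
  err_c <- vapply(ep_c, function(e) {
    ev <- sample_alpha_event(chc, e)
    stopifnot(length(ev$alpha_energies_mev) == 3)
    abs(sum(ev$product_energies_mev) - (e - 7.275))
  }, numeric(1))
  err_f <- vapply(ep_f, function(e) {
    ev <- sample_alpha_event(chf, e)
    stopifnot(length(ev$alpha_energies_mev) == 1)
    abs(sum(ev$product_energies_mev) - (e + 8.114))
  }, numeric(1))
  expect_lt(max(err_c), 1e-6)
  expect_lt(max(err_f), 1e-6)
  expect_error(sample_alpha_event(chc, 5), "below")
})

test_that("phase-space alpha energies match the analytic microcanonical mean", {
  ch <- builtin_channels()$C12_p_3alpha
  ep <- 20
  e_tot <- ep + ch$q_value_mev
  masses <- c(4.002602, 4.002602, 4.002602, 1.007825)
  # <T_alpha> = E_tot (1 - m_alpha / M) / (N - 1) for uniform
  # non-relativistic phase space
  analytic <- e_tot * (1 - masses[1] / sum(masses)) / 3
  set.seed(7)
  draws <- vapply(seq_len(1e4), function(i) {
    sample_alpha_event(ch, ep)$alpha_energies_mev[1]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - analytic), 3 * se)
})

test_that("removing the target reduces the pair exactly to the background channel", {
  beam <- build_sobp(n_peaks = 5)
  ps <- in_tumor_proton_spectrum(beam, n_protons = 1e4, seed = 2)
  none <- alpha_spectrum_pair(ps, NULL, n_events = 5e3, seed = 9)
  expect_identical(none$with$fluence, none$without$fluence)
  carbon <- alpha_spectrum_pair(ps, nano_geometry(), n_events = 5e3, seed = 9)
  # same seed: identical background draws
  expect_identical(carbon$without$fluence, none$without$fluence)
  expect_true(all(carbon$with$fluence >= carbon$without$fluence))
})

test_that("the carbon-target alpha excess concentrates in the 1-6 MeV band", {
  beam <- build_sobp()
  ps <- in_tumor_proton_spectrum(beam, n_protons = 5e4, seed = 3)
  pair <- alpha_spectrum_pair(ps, nano_geometry(), n_events = 2e4, seed = 5)
  excess <- pair$with$fluence - pair$without$fluence
  ctr <- bin_centers(pair$with)
  expect_gt(sum(excess[ctr > 1 & ctr < 6]) / sum(excess), 0.5)
})

test_that("total with-target yield matches the Poisson/forced-weight expectation", {
  beam <- build_sobp()
  ps <- in_tumor_proton_spectrum(beam, n_protons = 5e4, seed = 3)
  n_ev <- 2e4
  pair <- alpha_spectrum_pair(ps, nano_geometry(), n_events = n_ev, seed = 5)
  excess_total <- sum(pair$with$fluence) - sum(pair$without$fluence)
  # oracle: 3 x P_C x (probability a sampled proton is above threshold),
  # integrating the proton spectrum bin-by-bin with uniform-in-bin energies
  ch <- builtin_channels()$C12_p_3alpha
  p_c <- interaction_probability(ch, nano_geometry(), 20)
  ctr_frac <- mapply(function(lo, hi) {
    max(0, min(hi, 33) - max(lo, ch$threshold_mev)) / (hi - lo)
  }, ps$bin_low, ps$bin_high)
  p_open <- sum(ps$fluence * ctr_frac) / sum(ps$fluence)
  expected <- 3 * p_c * p_open
  se <- 3 * p_c * sqrt(p_open * (1 - p_open) / n_ev)
  expect_lt(abs(excess_total - expected), 3 * se)
})

test_that("alpha yields scale linearly with event count in expectation", {
  beam <- build_sobp()
  ps <- in_tumor_proton_spectrum(beam, n_protons = 2e4, seed = 3)
  p1 <- alpha_spectrum_pair(ps, nano_geometry(), n_events = 4e3, seed = 13)
  p2 <- alpha_spectrum_pair(ps, nano_geometry(), n_events = 16e3, seed = 13)
  c1 <- sum(p1$with$count)
  c2 <- sum(p2$with$count)
  expect_lt(abs(c2 / c1 - 4), 4 / sqrt(c1) * 3)
})
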