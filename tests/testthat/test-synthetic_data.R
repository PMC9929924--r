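test_that("simulated envelope peaks sit at (M + z*proton)/z", {
  sp <- species_model(1, 1, mass = 132091, mean_charge = 24.5, charge_sd = 1)
  cfg <- sim_config(seed = 1, noise_sd = 0)
  spec <- simulate_native_spectrum(sp, cfg, mz_range = c(4500, 6500))
  pk <- detect_peaks(spec, window_mz = cfg$peak_width_mz)
  expected <- (132091 + (23:26) * PROTON) / (23:26)
  for (mz in expected) {
    expect_true(any(abs(pk$mz - mz) < 0.5),
                label = sprintf("peak near m/z %.1f", mz))
  }
  # arithmetic anchors of the series ends
  expect_equal(min(abs(pk$mz - 5744.09)) < 1, TRUE)
  expect_equal(min(abs(pk$mz - 5081.43)) < 1, TRUE)
})

test_that("spectrum synthesis conserves injected abundance", {
  # single charge state: envelope collapses onto z = 24
  sp <- species_model(1, 0, mass = 132091, mean_charge = 24, charge_sd = 0.05,
                      abundance = 3.7)
  cfg <- sim_config(seed = 1, noise_sd = 0, baseline = 0)
  spec <- simulate_native_spectrum(sp, cfg, mz_range = c(5000, 6000))
  total <- sum((spec$intensity[-1] + spec$intensity[-length(spec$intensity)]) / 2 *
                 diff(spec$mz))
  expect_equal(total, 3.7, tolerance = 1e-6)

  # several species: summed area equals summed abundance
  species <- list(
    species_model(1, 0, 71459, 16, 1, abundance = 2),
    species_model(0, 1, 60632, 15, 1, abundance = 1.5))
  spec2 <- simulate_native_spectrum(species, cfg, mz_range = c(3000, 6000))
  total2 <- sum((spec2$intensity[-1] + spec2$intensity[-length(spec2$intensity)]) / 2 *
                  diff(spec2$mz))
  expect_equal(total2, 3.5, tolerance = 1e-6)
})

test_that("generators are reproducible given the seed", {
  sp <- species_model(1, 1, 132091, 24.5, 1)
  cfg <- sim_config(seed = 99, noise_sd = 0.02)
  a <- simulate_native_spectrum(sp, cfg, mz_range = c(4500, 6500))
  b <- simulate_native_spectrum(sp, cfg, mz_range = c(4500, 6500))
  expect_identical(a$intensity, b$intensity)
  c <- simulate_native_spectrum(sp, sim_config(seed = 100, noise_sd = 0.02),
                                mz_range = c(4500, 6500))
  expect_false(identical(a$intensity, c$intensity))

  t1 <- simulate_anisotropy_titration(1e-7, config = cfg)
  t2 <- simulate_anisotropy_titration(1e-7, config = cfg)
  expect_identical(t1$anisotropy, t2$anisotropy)

  truth <- lfer_truth(6.639, 5.3)
  r1 <- simulate_cid_ramp(complex_species_wt(), truth, replicates = 2,
                          config = cfg)
  r2 <- simulate_cid_ramp(complex_species_wt(), truth, replicates = 2,
                          config = cfg)
  expect_identical(r1[[2]]$spectra[[5]]$intensity,
                   r2[[2]]$spectra[[5]]$intensity)
})

test_that("ramp generator follows the study design and the LFER logistic", {
  truth <- lfer_truth(dg0_over_T = 66.4, n_slope = 50)
  cfg <- sim_config(seed = 3, noise_sd = 0)
  ramps <- simulate_cid_ramp(complex_species_wt(), truth,
                             voltages = seq(100, 240, 10), replicates = 2,
                             config = cfg)
  expect_length(ramps, 2)
  expect_length(ramps[[1]]$spectra, 15)
  expect_equal(ramps[[1]]$voltages, seq(100, 240, 10))

  # total ion current is conserved across the ramp (complex + product = 100)
  tics <- vapply(ramps[[1]]$spectra, function(s)
    sum((s$intensity[-1] + s$intensity[-length(s$intensity)]) / 2 * diff(s$mz)),
    numeric(1))
  expect_equal(tics, rep(100, 15), tolerance = 1e-6)

  # near-degenerate slope: intensity constant at the zero-energy logistic level
  flat <- lfer_truth(dg0_over_T = 6.639, n_slope = 1e-9)
  rf <- simulate_cid_ramp(complex_species_wt(), flat, replicates = 1,
                          config = cfg)
  cv <- extract_dissociation_curve(rf[[1]])
  expect_equal(cv$intensity_pct, rep(100 / (1 + exp(-6.639 / RGAS)), 15),
               tolerance = 1e-6)
})

test_that("anisotropy generator reproduces the one-site curve", {
  cfg0 <- sim_config(seed = 5, noise_sd = 0)
  kd <- 1e-7
  tit <- simulate_anisotropy_titration(kd, a_free = 0.05, a_bound = 0.25,
                                       concentrations = c(kd / 10, kd, 1000 * kd),
                                       replicates = 1, config = cfg0)
  a <- tit$anisotropy[, 1]
  expect_equal(a[2], (0.05 + 0.25) / 2, tolerance = 1e-12)  # half saturation
  expect_lt(abs(a[3] - 0.25) / 0.2, 0.001)                  # saturation limit

  # default series: 13-point two-fold dilution reaching 6.6 uM
  s <- dilution_series()
  expect_length(s, 13)
  expect_equal(max(s), 6.6e-6)
  expect_equal(unique(round(s[-1] / s[-13])), 2)
  expect_lt(min(s), 1.7e-9)
})

test_that("generator contracts reject invalid input", {
  cfg <- sim_config(seed = 1)
  expect_error(simulate_native_spectrum(list(), cfg), "non-empty")
  expect_error(simulate_cid_ramp(complex_species_wt(), lfer_truth(1, 1),
                                 voltages = numeric(0), config = cfg),
               "non-empty")
  expect_error(simulate_cid_ramp(complex_species_wt(), lfer_truth(1, 1),
                                 replicates = 0, config = cfg),
               "replicates")
  expect_error(simulate_anisotropy_titration(-1, config = cfg), "positive")
  expect_error(lfer_truth(1, -2), "n_slope")
  expect_error(lfer_truth(1, 1, top = 50, bottom = 60), "plateaus")
  expect_error(species_model(0, 0, 100, 10), "stoichiometry")
  expect_error(sim_config(), "seed")
})
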