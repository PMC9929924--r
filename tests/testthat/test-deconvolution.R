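test_that("peak detection finds isolated Gaussians and ignores flat signal", {
  grid <- seq(4000, 6000, by = 2)
  flat <- mass_spectrum(grid, rep(1, length(grid)))
  expect_equal(nrow(detect_peaks(flat, window_mz = 8)), 0)

  one <- mass_spectrum(grid, dnorm(grid, 5000, 8))  # unit area
  pk <- detect_peaks(one, window_mz = 8)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, 1, tolerance = 0.01)
  expect_equal(pk$mz, 5000, tolerance = 0.1)

  two <- mass_spectrum(grid, dnorm(grid, 4800, 8) + 2 * dnorm(grid, 5600, 8))
  pk2 <- detect_peaks(two, window_mz = 8)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$mz, c(4800, 5600), tolerance = 0.1)
  expect_equal(pk2$area[2] / pk2$area[1], 2, tolerance = 0.01)
})

test_that("charge series assignment recovers simulated masses", {
  cfg <- sim_config(seed = 2, noise_sd = 0)
  spec <- simulate_native_spectrum(
    species_model(1, 1, 132091, 24.5, 1), cfg, mz_range = c(4500, 6500))
  series <- assign_charge_series(detect_peaks(spec, window_mz = 8),
                                 z_range = 15:35)
  expect_length(series, 1)
  expect_lt(abs(series[[1]]$mass - 132091) / 132091, 5e-4)
  expect_true(all(23:26 %in% series[[1]]$charges))

  # mixture of the two monomers resolves into two series
  mix <- simulate_native_spectrum(
    list(species_model(1, 0, 71459, 16, 1, abundance = 2),
         species_model(0, 1, 60632, 14, 1, abundance = 1)),
    cfg, mz_range = c(3200, 6200))
  series2 <- assign_charge_series(detect_peaks(mix, window_mz = 8),
                                  z_range = 8:25)
  expect_length(series2, 2)
  masses <- sort(vapply(series2, function(s) s$mass, numeric(1)))
  expect_lt(abs(masses[1] - 60632) / 60632, 5e-4)
  expect_lt(abs(masses[2] - 71459) / 71459, 5e-4)

  # two isolated peaks are below the 3-consecutive-state minimum
  pk <- data.frame(mz = c(5000, 5200), area = c(1, 1),
                   apex_intensity = c(1, 1))
  expect_length(assign_charge_series(pk, z_range = 10:30), 0)
})

test_that("round trip recovers random species masses (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    mass <- runif(1, 5e4, 3e5)
    zbar <- round(mass / 5500)
    for (noise in c(0, 0.02)) {
      cfg <- sim_config(seed = seed + 10, noise_sd = noise)
      spec <- simulate_native_spectrum(
        species_model(1, 0, mass, zbar + 0.3, 1.2), cfg,
        mz_range = c(mass / (zbar + 6), mass / (zbar - 6)))
      series <- assign_charge_series(
        detect_peaks(spec, min_snr = 5, window_mz = 8),
        z_range = max(1, zbar - 12):(zbar + 12))
      expect_gte(length(series), 1)
      err <- abs(series[[1]]$mass - mass) / mass
      expect_lt(err, if (noise == 0) 5e-4 else 2e-3)
    }
  }
})

test_that("zero-charge spectrum concentrates series area at the right mass", {
  cfg <- sim_config(seed = 4, noise_sd = 0)
  spec <- simulate_native_spectrum(
    list(species_model(1, 1, 132091, 24.5, 1, abundance = 3),
         species_model(1, 0, 71459, 17, 0.8, abundance = 1)),
    cfg, mz_range = c(3400, 6500))
  series <- assign_charge_series(detect_peaks(spec, window_mz = 8),
                                 z_range = 10:35)
  zc <- zero_charge_spectrum(spec, series, mass_grid_step = 10)
  # apex near each true mass
  for (m in c(132091, 71459)) {
    apex <- zc$mass[which.max(zc$intensity * (abs(zc$mass - m) < 2000))]
    expect_lt(abs(apex - m), 100)
  }
  # area ratio matches injected abundance ratio
  a1 <- sum(zc$intensity[abs(zc$mass - 132091) < 2000])
  a2 <- sum(zc$intensity[abs(zc$mass - 71459) < 2000])
  expect_equal(a1 / a2, 3, tolerance = 0.05)
  # no series -> all-zero spectrum
  zc0 <- zero_charge_spectrum(spec, list())
  expect_true(all(zc0$intensity == 0))
})

test_that("species quantification is normalised to total ion current", {
  cfg <- sim_config(seed = 6, noise_sd = 0)
  solo <- simulate_native_spectrum(species_model(1, 1, 132091, 24.5, 1),
                                   cfg, mz_range = c(4500, 6500))
  s <- assign_charge_series(detect_peaks(solo, window_mz = 16),
                            z_range = 15:35)[[1]]
  expect_equal(quantify_species(solo, s), 1, tolerance = 0.01)

  # a species carrying half the total area quantifies to 0.5
  half <- simulate_native_spectrum(
    list(species_model(1, 1, 132091, 24.5, 1, abundance = 1),
         species_model(1, 0, 71459, 17, 0.8, abundance = 1)),
    cfg, mz_range = c(3400, 6500))
  series <- assign_charge_series(detect_peaks(half, window_mz = 16),
                                 z_range = 10:35)
  big <- series[[which.min(vapply(series, function(x)
    abs(x$mass - 132091), numeric(1)))]]
  expect_equal(quantify_species(half, big), 0.5, tolerance = 0.01)
  expect_error(quantify_species(solo, s, charge_subset = c(23, 99)), "subset")

  # abundance fractions of disjoint assigned species sum to 1 (noise 0)
  fr <- vapply(series, function(x) quantify_species(half, x), numeric(1))
  expect_equal(sum(fr), 1, tolerance = 0.01)
})

test_that("stoichiometry assignment ranks the additive composition first", {
  st <- assign_stoichiometry(132091, MASS_RECEPTOR_WT, MASS_CARGO)
  expect_equal(st$stoich_receptor[1], 1)
  expect_equal(st$stoich_cargo[1], 1)
  expect_lt(st$mass_error[1], 1e-6)

  st22 <- assign_stoichiometry(264182, MASS_RECEPTOR_WT, MASS_CARGO)
  expect_equal(unlist(st22[1, 1:2]), c(stoich_receptor = 2, stoich_cargo = 2))

  stm <- assign_stoichiometry(71459, MASS_RECEPTOR_WT, MASS_CARGO)
  expect_equal(unlist(stm[1, 1:2]), c(stoich_receptor = 1, stoich_cargo = 0))

  expect_equal(nrow(assign_stoichiometry(55555, MASS_RECEPTOR_WT, MASS_CARGO)), 0)

  # mass additivity property over random compositions
  set.seed(11)
  for (k in 1:20) {
    i <- sample(0:3, 1); j <- sample(0:3, 1)
    if (i + j == 0) j <- 1
    m <- i * MASS_RECEPTOR_WT + j * MASS_CARGO + rnorm(1, 0, 5)
    st <- assign_stoichiometry(m, MASS_RECEPTOR_WT, MASS_CARGO)
    expect_equal(unname(unlist(st[1, 1:2])), c(i, j))
  }
})

test_that("variant masses follow residue and modification arithmetic", {
  expect_equal(variant_mass(71459), 71459)
  m2d <- variant_mass(71459, substitutions = list(c("S", "D", 2)))
  expect_equal(m2d, 71459 + 2 * (115.0886 - 87.0782), tolerance = 1e-9)
  expect_equal(round(m2d), 71515)
  mp <- variant_mass(60632, modifications = list(c("phosphorylation", 1)))
  expect_equal(round(mp), 60712)
  expect_error(variant_mass(1000, substitutions = list(c("S", "X", 1))),
               "unknown residue: X")
  expect_error(variant_mass(1000, modifications = list(c("glycosylation", 1))),
               "unknown modification")
})
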