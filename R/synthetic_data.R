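#' Describe one gas-phase species for spectrum simulation
#'
#' A species is an (i receptor : j cargo) assembly with a given neutral mass
#' and a Gaussian charge-state envelope. The envelope is evaluated on integer
#' charges and truncated where its weight falls below 1e-4 of the mode, which
#' reproduces the narrow ion series (a handful of charge states) typical of
#' native electrospray of folded complexes.
#'
#' @param stoich_receptor,stoich_cargo Integer subunit counts (i, j), i+j >= 1.
#' @param mass Neutral species mass in Da.
#' @param mean_charge Centre of the charge envelope (elementary charges).
#' @param charge_sd Width of the envelope (charges), > 0.
#' @param abundance Relative amount (arbitrary units, >= 0); peak areas are
#'   proportional to it.
#' @return An object of class `species_model`.
#' @export
species_model <- function(stoich_receptor, stoich_cargo, mass, mean_charge,
                          charge_sd = 1, abundance = 1) {
  stoich_receptor <- as.integer(stoich_receptor)
  stoich_cargo <- as.integer(stoich_cargo)
  if (stoich_receptor < 0 || stoich_cargo < 0 ||
      stoich_receptor + stoich_cargo < 1)
    stop("stoichiometry counts must be >= 0 and sum to >= 1")
  if (mass <= 0) stop("mass must be positive")
  if (charge_sd <= 0) stop("charge_sd must be positive")
  if (abundance < 0) stop("abundance must be >= 0")
  structure(
    list(stoich_receptor = stoich_receptor, stoich_cargo = stoich_cargo,
         mass = as.numeric(mass), mean_charge = as.numeric(mean_charge),
         charge_sd = as.numeric(charge_sd), abundance = as.numeric(abundance)),
    class = "species_model"
  )
}

#' Ground truth for the linear free-energy dissociation model
#'
#' Defines the intact-complex percentage as a function of centre-of-mass
#' collision energy E_com through
#' `I(E) = bottom + (top - bottom) / (1 + exp(-(dg0_over_T - n_slope * E) / R))`,
#' the exact inverse of the Gibbs-energy transform used by the analysis, so
#' simulated ramps are invertible by construction.
#'
#' @param dg0_over_T Intercept, apparent activation free energy over
#'   temperature at zero collision energy (J mol^-1 K^-1). The implied
#'   dimensionless gas-phase dissociation constant is
#'   `exp(-dg0_over_T / R)`.
#' @param n_slope Slope n (J mol^-1 K^-1 per eV), > 0.
#' @param top,bottom Upper/lower intensity plateaus in percent of total ion
#'   current, `0 <= bottom < top <= 100`.
#' @return An object of class `lfer_truth`.
#' @export
lfer_truth <- function(dg0_over_T, n_slope, top = 100, bottom = 0) {
  if (n_slope <= 0) stop("n_slope must be positive")
  if (!(bottom >= 0 && bottom < top && top <= 100))
    stop("plateaus must satisfy 0 <= bottom < top <= 100")
  structure(
    list(dg0_over_T = as.numeric(dg0_over_T), n_slope = as.numeric(n_slope),
         top = as.numeric(top), bottom = as.numeric(bottom)),
    class = "lfer_truth"
  )
}

#' Simulation configuration
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (seed, parameters).
#' @param noise_sd Gaussian noise scale: for spectra, a fraction of the
#'   maximum noiseless signal; for ramps, a fraction of the dissociation
#'   dynamic range (top - bottom); for titrations, a fraction of the
#'   anisotropy amplitude.
#' @param peak_width_mz Gaussian peak sigma in Thomson.
#' @param baseline Constant intensity offset.
#' @param mz_step Grid spacing of simulated spectra (Thomson); defaults to a
#'   quarter of the peak width, fine enough for accurate area integration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, noise_sd = 0.02, peak_width_mz = 8,
                       baseline = 0, mz_step = peak_width_mz / 4) {
  if (missing(seed)) stop("a seed is mandatory")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (peak_width_mz <= 0) stop("peak_width_mz must be positive")
  structure(
    list(seed = as.integer(seed), noise_sd = as.numeric(noise_sd),
         peak_width_mz = as.numeric(peak_width_mz),
         baseline = as.numeric(baseline), mz_step = as.numeric(mz_step)),
    class = "sim_config"
  )
}

# Evaluate the Gaussian charge envelope on integer charges, truncated at
# weights < 1e-4 of the mode; optionally restricted to a fixed charge set.
charge_envelope <- function(mean_charge, charge_sd, charges = NULL) {
  if (is.null(charges)) {
    half <- ceiling(charge_sd * sqrt(2 * log(1e4))) + 1
    charges <- seq.int(max(1, floor(mean_charge) - half),
                       ceiling(mean_charge) + half)
    w <- exp(-(charges - mean_charge)^2 / (2 * charge_sd^2))
    keep <- w >= 1e-4 * max(w)
    charges <- charges[keep]; w <- w[keep]
  } else {
    charges <- as.integer(charges)
    w <- exp(-(charges - mean_charge)^2 / (2 * charge_sd^2))
  }
  list(charges = charges, weights = w / sum(w))
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Add Gaussian peaks (area-parameterised) for one species to an intensity
# vector on a fixed m/z grid.
.add_species_peaks <- function(intensity, grid, species, sigma,
                               charges = NULL, total_area = NULL) {
  env <- charge_envelope(species$mean_charge, species$charge_sd, charges)
  area <- if (is.null(total_area)) species$abundance else total_area
  for (k in seq_along(env$charges)) {
    z <- env$charges[k]
    centre <- (species$mass + z * .PROTON) / z
    intensity <- intensity +
      area * env$weights[k] * stats::dnorm(grid, centre, sigma)
  }
  intensity
}

#' Simulate a native mass spectrum
#'
#' Forward model of what the deconvolution stage must invert: for each
#' species and each integer charge z with non-negligible envelope weight, a
#' Gaussian peak centred at `(mass + z * 1.00728) / z` whose area is
#' `abundance * envelope_weight`; a constant baseline and additive Gaussian
#' noise (sd = `noise_sd` times the maximum noiseless signal) are applied
#' last and the result clipped at zero.
#'
#' @param species List of [species_model()] objects (or a single one).
#' @param config A [sim_config()].
#' @param mz_range Length-2 numeric, the simulated m/z window (Thomson).
#' @param accel_voltage,quad_cutoff_mz Optional instrument metadata stored on
#'   the returned spectrum.
#' @param label Spectrum label.
#' @return A [mass_spectrum()] on a uniform grid.
#' @export
simulate_native_spectrum <- function(species, config,
                                     mz_range = c(1000, 10000),
                                     accel_voltage = NA_real_,
                                     quad_cutoff_mz = NA_real_,
                                     label = "simulated") {
  if (inherits(species, "species_model")) species <- list(species)
  if (!length(species)) stop("species list must be non-empty")
  if (mz_range[1] <= 0 || diff(mz_range) <= 0)
    stop("mz_range must be positive and increasing")
  grid <- seq(mz_range[1], mz_range[2], by = config$mz_step)
  intensity <- rep(0, length(grid))
  for (sp in species)
    intensity <- .add_species_peaks(intensity, grid, sp, config$peak_width_mz)
  intensity <- intensity + config$baseline
  if (config$noise_sd > 0) {
    scale <- config$noise_sd * max(intensity)
    noise <- .with_seed(config$seed, stats::rnorm(length(grid), 0, scale))
    intensity <- pmax(intensity + noise, 0)
  }
  mass_spectrum(grid, intensity, accel_voltage = accel_voltage,
                quad_cutoff_mz = quad_cutoff_mz, label = label)
}

#' Simulate collision-induced dissociation voltage ramps
#'
#' For each acceleration voltage the centre-of-mass collision energy is
#' computed from the abundance-weighted mean charge of the complex envelope
#' (restricted to `charge_subset`, the states later used for
#' quantification), and the surviving intact-complex percentage follows the
#' linear free-energy logistic of [lfer_truth()]. Each simulated spectrum
#' carries the complex ion series with total area equal to the intact
#' percentage plus a single aggregate dissociation-product series at low
#' charge (outside `charge_subset`) carrying the complementary intensity, so
#' the total ion current is conserved at 100 per spectrum. Replicate
#' Gaussian noise with sd `noise_sd * (top - bottom)` is added to the intact
#' percentage before spectrum synthesis and clipped to [0, 100].
#'
#' @param complex_species A [species_model()] for the monitored 1:1 complex.
#' @param truth An [lfer_truth()].
#' @param voltages Ascending acceleration voltages (V).
#' @param replicates Number of replicate ramps (>= 1).
#' @param config A [sim_config()].
#' @param charge_subset Integer charges carrying the complex signal and used
#'   for quantification downstream.
#' @param gas_mass Collision gas mass (Da); argon by default.
#' @param mz_range Simulated m/z window; must cover both the complex series
#'   and the low-charge product series.
#' @return A list of [ramp_experiment()], one per replicate.
#' @export
simulate_cid_ramp <- function(complex_species, truth, voltages = seq(100, 240, 10),
                              replicates = 3, config,
                              charge_subset = 23:26,
                              gas_mass = ms_constants[["argon_mass"]],
                              mz_range = NULL) {
  if (!length(voltages)) stop("voltages must be non-empty")
  if (any(diff(voltages) <= 0)) stop("voltages must be strictly ascending")
  if (replicates < 1) stop("replicates must be >= 1")
  stopifnot(inherits(complex_species, "species_model"),
            inherits(truth, "lfer_truth"))

  env <- charge_envelope(complex_species$mean_charge,
                         complex_species$charge_sd, charge_subset)
  zbar <- sum(env$charges * env$weights)
  ecom <- vapply(voltages, function(v)
    center_of_mass_energy(zbar, v, complex_species$mass, gas_mass), numeric(1))
  intact <- truth$bottom + (truth$top - truth$bottom) /
    (1 + exp(-(truth$dg0_over_T - truth$n_slope * ecom) / .RGAS))

  # aggregate dissociation product: half the complex mass at roughly a
  # quarter of the complex charge, well outside the quantified series
  prod_species <- species_model(0, 1, mass = complex_species$mass / 2,
                                mean_charge = max(2, round(complex_species$mean_charge / 4)),
                                charge_sd = 0.7)
  if (is.null(mz_range)) {
    lo <- 0.9 * (complex_species$mass + min(charge_subset) * .PROTON) / max(charge_subset)
    hi <- 1.35 * prod_species$mass / max(1, prod_species$mean_charge - 2)
    mz_range <- c(lo, hi)
  }
  grid <- seq(mz_range[1], mz_range[2], by = config$mz_step)

  noise <- .with_seed(config$seed,
    matrix(stats::rnorm(replicates * length(voltages), 0,
                        config$noise_sd * (truth$top - truth$bottom)),
           nrow = replicates))

  lapply(seq_len(replicates), function(r) {
    spectra <- lapply(seq_along(voltages), function(i) {
      I <- min(max(intact[i] + noise[r, i], 0), 100)
      intensity <- rep(0, length(grid))
      intensity <- .add_species_peaks(intensity, grid, complex_species,
                                      config$peak_width_mz,
                                      charges = charge_subset, total_area = I)
      intensity <- .add_species_peaks(intensity, grid, prod_species,
                                      config$peak_width_mz,
                                      total_area = 100 - I)
      mass_spectrum(grid, intensity + config$baseline,
                    accel_voltage = voltages[i],
                    label = sprintf("ramp rep %d, %g V", r, voltages[i]))
    })
    ramp_experiment(spectra, replicate_id = r,
                    complex_mass = complex_species$mass,
                    charge_subset = charge_subset)
  })
}

#' Default anisotropy dilution series
#'
#' Thirteen-point two-fold serial dilution of the receptor from 6.6 uM down
#' (lowest point 1.6 nM), the design used for the Lys1p, Cat2p and Pcs60p
#' peptide titrations.
#'
#' @param top Highest concentration (molar).
#' @param points Number of dilution points.
#' @return Increasing numeric vector of concentrations (molar).
#' @export
dilution_series <- function(top = 6.6e-6, points = 13) {
  sort(top / 2^(seq_len(points) - 1))
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Mean anisotropy follows the one-site binding-saturation curve
#' `A(c) = a_free + (a_bound - a_free) * c / (kd + c)`; independent Gaussian
#' noise with sd `noise_sd * |a_bound - a_free|` is added per replicate
#' reading.
#'
#' @param kd True dissociation constant (molar), > 0.
#' @param a_free,a_bound Anisotropy of the free and fully bound probe.
#' @param concentrations Receptor concentrations (molar); defaults to
#'   [dilution_series()].
#' @param replicates Replicate readings per concentration.
#' @param config A [sim_config()]; `noise_sd` is interpreted relative to the
#'   amplitude `|a_bound - a_free|`.
#' @param probe_conc Labelled-peptide concentration (molar), metadata only.
#' @return An [anisotropy_titration()].
#' @export
simulate_anisotropy_titration <- function(kd, a_free = 0.05, a_bound = 0.25,
                                          concentrations = dilution_series(),
                                          replicates = 3, config,
                                          probe_conc = 10e-9) {
  if (kd <= 0) stop("kd must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  concentrations <- sort(concentrations)
  mean_a <- a_free + (a_bound - a_free) * concentrations / (kd + concentrations)
  noise <- .with_seed(config$seed,
    matrix(stats::rnorm(length(concentrations) * replicates, 0,
                        config$noise_sd * abs(a_bound - a_free)),
           ncol = replicates))
  anisotropy_titration(concentrations, mean_a + noise,
                       probe_conc = probe_conc,
                       label = sprintf("simulated kd=%.3g M", kd))
}
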