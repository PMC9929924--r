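# Shared fixtures for the test suite. All synthetic inputs are built in code.

RGAS <- 8.31446
PROTON <- 1.00728
ARGON <- 39.948

# Printed reference masses (Da) of the receptor variants, the cargo and
# their complexes, used across deconvolution and acceptance tests.
MASS_RECEPTOR_WT <- 71459
MASS_RECEPTOR_2D <- 71515
MASS_CARGO <- 60632

# Default 1:1 complex species for ramp simulations
complex_species_wt <- function(abundance = 1) {
  species_model(1, 1, mass = MASS_RECEPTOR_WT + MASS_CARGO,
                mean_charge = 24.5, charge_sd = 1, abundance = abundance)
}

# Intact percentage implied by a linear free-energy truth at energy E --
# an independent closed-form oracle for generator/extraction tests.
lfer_intensity <- function(truth, e_com) {
  truth$bottom + (truth$top - truth$bottom) /
    (1 + exp(-(truth$dg0_over_T - truth$n_slope * e_com) / RGAS))
}

# Direct arithmetic for the centre-of-mass energy, kept separate from the
# package implementation.
ecom_oracle <- function(z, v, mass, gas = ARGON) z * v * gas / (gas + mass)

# A bare dissociation-curve-like record from explicit vectors (bypasses
# spectrum synthesis for fitter-only tests).
make_curve <- function(e_com, intensity_pct) {
  list(e_com = e_com, intensity_pct = intensity_pct)
}
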