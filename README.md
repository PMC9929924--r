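# nativems

Native mass spectrometry of intact protein complexes can report on complex
stoichiometry and on the relative stability of noncovalent interactions.
`nativems` implements the analysis pipeline for one such system — the yeast
peroxisomal import receptor Pex5p bound to its PTS1 cargo protein Pcs60p —
as reusable, tested R code for anyone analysing collision-induced
dissociation (CID) stability ramps or fluorescence-anisotropy peptide
titrations:

- **Charge-state deconvolution** — peak picking, assignment of multi-charge
  ion series, zero-charge mass spectra, and quantification of species
  abundance relative to total ion current (TIC).
- **Stoichiometry by mass additivity** — explaining a deconvolved complex
  mass as *i*·M(receptor) + *j*·M(cargo), and average-mass arithmetic for
  sequence variants (e.g. the phosphomimetic S→D exchange, +28.01 Da each)
  and modifications (phosphorylation, +79.97 Da).
- **CID dissociation curves** — centre-of-mass collision energy
  E<sub>com</sub> = z̄·V·m<sub>gas</sub>/(m<sub>gas</sub> + m<sub>ion</sub>)
  from the abundance-weighted mean charge z̄, Boltzmann sigmoid fits
  (Levenberg–Marquardt), and F-statistic profile confidence intervals.
- **Gas-phase dissociation constants** — the transform
  ΔG<sup>#</sup>/T = −R·ln((100 − I)/I) of the intact-complex percentage
  *I*, a linear free-energy fit ΔG<sup>#</sup>/T = ΔG<sub>0</sub><sup>#</sup>/T − n·E<sub>com</sub>,
  and extrapolation to zero collision energy giving the dimensionless
  apparent constant K<sub>D</sub><sup>#</sup> = exp(−ΔG<sub>0</sub><sup>#</sup>/T / R).
- **Anisotropy binding fits** — one-site binding-saturation fits
  A(c) = A<sub>free</sub> + (A<sub>bound</sub> − A<sub>free</sub>)·c/(K<sub>D</sub> + c)
  of labelled-peptide titrations, experiment summaries, and fold-change
  comparisons between receptor variants.
- **Seeded synthetic-data generators** for all three data kinds, so the
  entire pipeline is testable without instrument data.

## Worked example

Simulate triplicate CID ramps (100–240 V in 10-V steps, charge states
+23…+26, argon collision gas, 2% replicate noise) for a 132,091-Da 1:1
complex whose ground-truth intercept corresponds to K<sub>D</sub><sup>#</sup> = 0.45,
then recover the constant through the full pipeline:

```r
library(nativems)
R <- ms_constants[["gas_constant"]]

truth <- lfer_truth(dg0_over_T = -R * log(0.45), n_slope = 5.3)
cplx  <- species_model(1, 1, mass = 132091, mean_charge = 24.5, charge_sd = 1)
ramps <- simulate_cid_ramp(cplx, truth, replicates = 3,
                           config = sim_config(seed = 1, noise_sd = 0.02))
estimate_kd_from_ramps(ramps)
#> <kd_summary> K_D^# = 0.441 +/- 0.0124 (n = 3)
```

The summary is the mean ± SD of per-replicate linear free-energy fits; each
replicate looks like

```r
estimate_kd_from_ramps(ramps)$fits[[1]]
#> <lfer_fit> dG0#/T 6.653 J/mol/K, n 5.182 J/mol/K/eV, R^2 0.9041, K_D^# 0.4493 (15 points)
```

i.e. an intercept of ~6.65 J·mol⁻¹·K⁻¹ extrapolated to zero collision
energy, which the exponential transform turns into a dimensionless
dissociation constant near the true 0.45. Stoichiometry and binding fits
work the same way:

```r
assign_stoichiometry(132091, receptor_mass = 71459, cargo_mass = 60632)
#>   stoich_receptor stoich_cargo mass_error
#> 1               1            1          0

tit <- simulate_anisotropy_titration(kd = 88.81e-9,
                                     config = sim_config(seed = 1, noise_sd = 0.02))
fit_one_site(tit)
#> <binding_fit> K_D = 8.316e-08 M, a_free 0.0484, a_bound 0.2493, ssr 0.000436

fold_change(0.45, 4.7)$ratio   # gas-phase WT vs phosphomimetic receptor
#> [1] 10.44444
```

A command-line wrapper with `simulate`, `deconvolve`, `cidfit`, `kd` and
`anisofit` subcommands is installed at
`system.file("scripts/nativems", package = "nativems")`.

## Further reading

The methods vignette (`vignettes/receptor-cargo-stability.Rmd`) describes
the models, their assumptions, the numerical choices, what the synthetic
generators do and do not emulate, and known limitations.
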