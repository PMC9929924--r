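---
title: "Receptor-cargo complex stability by native MS and anisotropy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-cargo complex stability by native MS and anisotropy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativems)
```

`nativems` analyses two complementary readouts of how tightly a peroxisomal
import receptor (Pex5p, ~71.5 kDa) holds its PTS1 cargo (Pcs60p,
~60.6 kDa): the gas-phase stability of the intact 1:1 complex probed by
collision-induced dissociation (CID) in a native mass spectrometer, and
solution-phase peptide affinities measured by fluorescence anisotropy. This
vignette explains the models behind each stage, the tunable parameters, the
synthetic-data generators used for validation, and the numerical choices
and limitations a user should know about.

## Charge-state deconvolution

Electrosprayed folded complexes appear as a narrow series of charge states.
A peak at mass-to-charge $m/z$ carrying $z$ protons implies a neutral mass

$$M = z \,(m/z - 1.00728),$$

with 1.00728 Da per proton. `detect_peaks()` finds local maxima above a
robust threshold (median plus `min_snr` median-absolute-deviations of the
intensity), refines apex positions by log-parabolic interpolation — exact
for Gaussian peaks — and integrates a trapezoidal area over $\pm 3$ times
the supplied peak width. `assign_charge_series()` then searches candidate
charges greedily: a series is accepted only when at least **three
consecutive** charge states agree on $M$ within `mass_rel_tol` (default
$10^{-3}$, matching kDa-level mass reporting). Two-state series are
rejected as ambiguous, because one can nearly always explain two peaks with
some other $(M, z)$ pair; ties between charge hypotheses go to the smaller
relative mass spread. The series mass is the area-weighted mean of the
per-peak estimates.

Species abundance is quantified by `quantify_species()` as summed peak area
over the total ion current (the trapezoidal integral of the whole
spectrum), the normalisation that makes abundances comparable across
spectra of a voltage ramp.

Stoichiometry follows from mass additivity: `assign_stoichiometry()`
enumerates compositions $i \cdot M_\text{receptor} + j \cdot
M_\text{cargo}$ up to `max_units` of each (default 6, since the cargo alone
can form low-abundance tetramers and hexamers) and ranks them by absolute
mass error. With the monomer masses 71,459 Da (wild-type receptor),
71,515 Da (S507D/S523D phosphomimetic) and 60,632 Da (cargo), the observed
complexes at 132,091 / 132,147 / 192,723 / 264,182 Da are explained exactly
by 1:1, 1:1, 1:2 and 2:2 compositions. `variant_mass()` does the
complementary arithmetic with **average** residue masses (appropriate for
intact-protein measurements): two serine-to-aspartate exchanges add
$2 \times (115.0886 - 87.0782) = 56.02$ Da, turning 71,459 into 71,515 Da.

## Dissociation curves and the Boltzmann sigmoid

In a CID ramp the trap acceleration voltage $V$ is stepped (here 100–240 V
in 10-V steps) and the surviving intact-complex percentage $I$ is recorded.
The laboratory-frame energy $zV$ is scaled to the centre-of-mass frame of
the ion-gas collision,

$$E_\mathrm{com} = \bar z \, V \, \frac{m_\text{gas}}{m_\text{gas} + m_\text{ion}} \quad \text{(eV)},$$

with argon ($m = 39.948$ Da) and $\bar z$ the abundance-weighted mean
charge of the quantified series (charge states +23…+26 by default). The
formula is the standard two-body kinematic result; it is the only form
consistent with eV-scale energies for a ~132-kDa ion at a few thousand
volts-equivalent of lab energy.

`fit_boltzmann()` fits the decreasing sigmoid

$$I(E) = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + e^{(E - E_{50})/w}}$$

by Levenberg–Marquardt least squares (`minpack.lm`), with the lower plateau
bounded at zero (optionally pinned to zero), five restarts from jittered
data-driven starting values, and, by default, fitting the across-replicate
mean curve (`fit_to_mean = TRUE`) with replicate dispersion available
separately. $E_{50}$ is the energy at which half the complexes have
dissociated. Confidence intervals use the single-parameter profile rule:
fixing the parameter on a grid, refitting the rest, and bounding the region
where

$$SSR(\theta) \le SSR_\text{min}\left(1 + \frac{F(p;\,1,\,\text{dof})}{\text{dof}}\right),$$

with bisection refinement to $10^{-4}$ relative. At $p = 0.68$ this
corresponds to a one-standard-deviation interval; its empirical coverage is
checked by simulation in the test suite (500 Monte-Carlo repeats of a
15-point curve at 2-percentage-point noise).

## The gas-phase dissociation constant

Treating dissociation as a two-state equilibrium at an unknown effective
temperature $T$, the intact percentage maps onto an apparent free energy
per kelvin:

$$\frac{\Delta G^{\#}}{T} = -R \,\ln\!\frac{100\% - I}{I},$$

with $R = 8.31446$ J·mol⁻¹·K⁻¹. $T$ is never materialised — every quantity
is carried as $G/T$. Plotting $\Delta G^{\#}/T$ against $E_\mathrm{com}$
and assuming a linear free-energy relationship,

$$\frac{\Delta G^{\#}}{T} = \frac{\Delta G_0^{\#}}{T} - n\,E_\mathrm{com},$$

the intercept extrapolates to zero external activation, and

$$K_D^{\#} = e^{-\frac{\Delta G_0^{\#}/T}{R}}$$

is the dimensionless apparent gas-phase dissociation constant.
`estimate_kd_from_ramps()` runs extraction, transformation and fitting per
replicate and reports the mean ± SD of $K_D^{\#}$ across replicates.
Published values of this kind carry a ± whose meaning (replicate SD versus
fit uncertainty) is rarely stated; the replicate SD is the reproducible
choice and is what this package reports, with pooled fitting available via
`pooled = TRUE`.

Two numerical rules matter here:

- **Plateau exclusion.** The log-transform diverges as $I \to 0$ or
  $I \to 100$. Points with $I \le 0.5\%$ or $\ge 99.5\%$ are *excluded*
  (not clipped): clipping would inject fabricated extreme free energies
  into the line fit.
- **Integration width.** Curve extraction integrates peak areas over
  $\pm 6$ peak sigma. A $\pm 3\sigma$ window misses 0.27% of a Gaussian
  area, which is invisible in a figure but caps the accuracy of the
  noise-free pipeline identity (generator → analysis) at roughly three
  significant digits; $\pm 6\sigma$ keeps the truncation below $10^{-8}$
  and the identity holds to better than six digits, which the tests
  enforce.

## One-site anisotropy fits

A fluorescently labelled peptide (10 nM) tumbling freely has low
anisotropy; bound to the ~71-kDa receptor it tumbles slowly and anisotropy
rises. With receptor in large excess over probe, the one-site saturation
model

$$A(c) = A_\text{free} + (A_\text{bound} - A_\text{free})\,\frac{c}{K_D + c}$$

is fitted unweighted to all replicate points (`fit_one_site()`). No
ligand-depletion correction is applied by default — at 10 nM probe and
$K_D \gtrsim 90$ nM the correction is negligible — but an exact quadratic
variant is available via `depletion = TRUE` for users whose probe
concentration approaches $K_D$. A fit is flagged **unsaturated** when the
fitted $K_D$ exceeds half the highest titrated concentration: the curve top
is then an extrapolation, which is exactly the regime reported for the
weakest receptor-peptide pairs, and the flag makes that failure mode a
visible property of the result rather than a silent number.
`summarize_experiments()` averages $K_D$ over independent experiments
(mean ± SD, with SD reported as absent for a single experiment), and
`fold_change()` forms variant-to-variant affinity ratios with first-order
error propagation; the measured constants give ratios of ~19.4 (solution,
full-length proteins) and ~10.4 (gas phase).

## What the synthetic generators emulate

The generators exist so that every downstream stage has a forward model it
provably inverts.

- `simulate_native_spectrum()` lays Gaussian peaks (area = abundance ×
  envelope weight) at $(M + z \cdot 1.00728)/z$ for integer charges under a
  Gaussian charge envelope truncated at $10^{-4}$ of its mode, plus
  baseline and additive Gaussian noise. Defaults: peak sigma 8 Th (broad
  native-MS peaks of a ~132-kDa complex), grid step sigma/4, noise 2% of
  the maximum signal. The instrument noise magnitude is not something the
  study reports; 2% is a fixture choice, not a claim.
- `simulate_cid_ramp()` computes $E_\mathrm{com}$ from the
  abundance-weighted mean charge and sets the intact percentage by the
  logistic that is the exact inverse of the $\Delta G^{\#}/T$ transform
  under the linear free-energy model, adds replicate noise (SD = 2% of the
  dissociation dynamic range by default) and synthesises one spectrum per
  voltage: the complex series plus a single aggregate dissociation-product
  series at low charge, conserving total ion current. Two deliberate
  choices: the complex envelope is **restricted to the quantified charge
  subset** (+23…+26, renormalised) so that the intensity carried by the
  quantified states equals the model's $I$ — with a wider envelope the
  quantified subset would see only ~87% of the complex signal and the exact
  inversion identity could not hold; and the product is a generic aggregate
  because the pipeline only needs the complex series and the TIC, not
  product identities. The slope is not a published quantity; the default
  $n = 5.3$ J·mol⁻¹·K⁻¹·eV⁻¹ places the wild-type half-dissociation point
  (intercept/slope ≈ 1.26 eV) mid-way through the 100–240 V window, as
  observed for curves of this kind.
- `simulate_anisotropy_titration()` draws replicate readings around the
  one-site curve (noise SD = 2% of the anisotropy amplitude) on a 13-point
  two-fold dilution series topping out at 6.6 µM.

All generators are pure functions of (seed, parameters); the global RNG
state is saved and restored around each call.

What they do **not** emulate: isotope structure, adducts, overlapping
envelopes of near-isobaric species, detector saturation, m/z-dependent
transmission, chemical background, or drift between replicates. Passing
the round-trip tests therefore demonstrates correctness of the inversion
logic and fitting machinery, not robustness to every artefact of real
spectra — in particular, real deconvolution of heavily overlapping
envelopes needs iterative tools beyond the greedy series assignment used
here.

## Problem sizes and test design

The validation suite runs entirely on generated data: ramp inversions use
the full 15-voltage × 3-replicate design; mass round-trip properties sample
random species of 50–300 kDa at zero and 2% noise; anisotropy recovery uses
60 random true constants between 50 nM and 1 µM at the study design; and
the profile-interval coverage check uses 500 Monte-Carlo repeats of a
15-point sigmoid, chosen to estimate a 68% coverage probability to roughly
±4 percentage points. Acceptance-level recoveries of the gas-phase
constants simulate three replicate ramps per variant, and anisotropy
constants three independent triplicate experiments, mirroring the reported
experimental designs.

## Known limitations

- The greedy charge-series assignment claims each peak once; strongly
  overlapping envelopes or series sharing peaks will shadow the weaker
  species.
- $K_D^{\#}$ is an apparent, dimensionless gas-phase quantity; it ranks
  variant stabilities but is not comparable in absolute value to a
  solution-phase $K_D$, and no conversion is attempted.
- The linear free-energy form is assumed, not tested, by the estimator;
  curvature in $\Delta G^{\#}/T$ versus $E_\mathrm{com}$ shows up only as
  reduced $r^2$ in the per-replicate fits.
- Unsaturated titrations return extrapolated constants whose bias grows
  with $K_D$ beyond the highest concentration; the flag, not the number,
  carries that information.
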