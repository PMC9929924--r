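Package: nativems
Title: Native Mass Spectrometry Analysis of Receptor-Cargo Complex Stability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the stability and stoichiometry of noncovalent
    protein complexes by native electrospray mass spectrometry, built around the
    peroxisomal import receptor Pex5p and its PTS1 cargo Pcs60p. Provides simple
    charge-state deconvolution (peak picking, charge-series assignment,
    zero-charge spectra), stoichiometry assignment by mass additivity,
    quantification of complex abundance relative to total ion current,
    collision-induced dissociation voltage ramps with Boltzmann sigmoid fits and
    F-statistic profile confidence intervals, estimation of dimensionless
    apparent gas-phase dissociation constants by linear free-energy
    extrapolation to zero collision energy, and one-site binding-saturation fits
    of fluorescence-anisotropy peptide titrations. Seeded synthetic-data
    generators emulate charge-state envelopes, dissociation ramps and anisotropy
    dilution series so the whole pipeline can be exercised and validated without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
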