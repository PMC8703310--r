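Package: phosfit
Title: Phosphorus-31 MRS Basis Simulation and Linear-Combination Fitting
Version: 0.1.0
Authors@R: person("MRS", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative in vivo phosphorus-31 magnetic resonance
    spectroscopy at clinical field strength. Provides a curated registry of
    phosphorus metabolite chemical shifts, multiplicities and J-couplings
    measured in phantoms at physiological pH; a first-order multiplet
    simulator producing Lorentzian basis spectra with or without proton
    decoupling; a frequency-domain linear-combination fitter with penalized
    spline baseline, Gaussian priors on phase and frequency adjustments, and
    Cramer-Rao lower bound reporting; Henderson-Hasselbalch pH estimation
    from the inorganic phosphate to phosphocreatine shift difference; and a
    seeded generator of phantom-like and tissue-like spectra with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
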