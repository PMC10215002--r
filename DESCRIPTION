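Package: seedperturb
Title: Dose-Perturbation Analysis Around High-Z Brachytherapy Seeds
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies localized dose perturbations (build-up and
    build-down) around high atomic number implants such as iodine-125
    brachytherapy seeds in external photon beams. Provides a data model
    for 2D dose maps and 1D cross-plane profiles, the relative
    dose-difference statistic, a film-protocol profile pipeline (axis
    averaging, flat-area normalization, 0.1 mm rebinning,
    symmetrization), a sign-constrained Gaussian-Lorentzian composite
    peak fit with numeric FWHM extraction, quadrature uncertainty
    budgets, a synthetic dose-map generator with ground-truth
    perturbations for recovery testing, and rotational multi-field
    superposition to study perturbation cancellation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
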