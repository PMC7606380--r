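Package: afmje
Title: Adsorption Free Energies from Single-Molecule Pulling, Surface Kinetics
    and Mean-Force Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recovers equilibrium adsorption free energies from noisy
    single-molecule pulling data. Screens atomic-force-microscopy retraction
    force-distance curves for single binding events with a five-step automated
    procedure (rupture detection by windowed derivatives, baseline alignment,
    noise-thresholded binding-minimum detection, bound-state location, and
    worm-like-chain fitting), integrates the external work per event, and
    estimates the free energy with three Jarzynski-equality estimators: the
    exponential-mean estimator, the fluctuation-dissipation estimator, and a
    closed-form estimator based on a maximum-likelihood gamma fit of the work
    distribution. Cross-validation utilities fit Langmuir kinetics to surface
    plasmon resonance coverage traces (association/dissociation rates and the
    dissociation constant) and integrate potential-of-mean-force profiles into
    state-partitioned adsorption free energies. Seeded generators produce every
    synthetic input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
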