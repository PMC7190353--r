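Package: axonmech
Title: Crosslinker Unfolding Model of Axonal Tension Buffering and Stretch Rheology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the viscoelastic stretch response of axons as a population of
    worm-like-chain crosslinkers (spectrin tetramers and similar proteins) whose
    rest length evolves by tension-dependent unfolding and refolding of repeat
    domains. Provides the steady-state tension-versus-strain solver, analytic and
    numeric tension relaxation times, stiff-ODE simulation of step-strain
    protocols, a stretch-rheology pipeline that converts cantilever force records
    into strain, tension, effective Young's moduli and double-exponential
    relaxation fits, autocorrelation analysis of spectrin periodicity in
    fluorescence line scans, order-of-magnitude estimators for the axonal
    cross-section, and seeded synthetic-data generators with attached ground
    truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
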