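Package: dnaforceps
Title: Single-Molecule DNA Forceps Analysis of NHEJ End Synapsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for magnetic-tweezer "molecular forceps"
    assays of non-homologous end joining (NHEJ) end synapsis. Provides
    worm-like-chain predictions of the extension change expected upon end
    synapsis for a forceps DNA construct, a seeded synthetic trace generator
    with planted ground-truth events under a two-level force-modulation
    protocol, rupture-event detection and amplitude-based specificity
    classification, two-component Gaussian amplitude deconvolution, censored
    exponential lifetime estimation, single-site and Hill binding-curve fits
    for microscale thermophoresis titrations, and condition-level synaptic
    efficiency summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
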