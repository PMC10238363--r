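Package: spectlab
Title: Simulation and Evaluation of Liver-Lesion Detectability in
    In-111 Octreotide SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how reconstruction choices affect the
    detectability of small liver lesions in In-111 octreotide SPECT.
    Generates synthetic abdominal phantoms with spatially correlated
    liver uptake, simulates projection data with an analytic attenuated
    projector and a Monte Carlo photon-transport projector (attenuation,
    Compton scatter, distance-dependent collimator response, photopeak
    energy windows), inserts spherical lesions into sinograms at a
    prescribed tumor-to-normal concentration ratio, reconstructs with
    ordered-subset expectation maximization (attenuation-corrected and
    Monte Carlo based arms), applies Butterworth and Gaussian post
    filters, and evaluates detectability via tumor-to-normal
    concentration ratios, signal-to-noise ratios, case-level
    classification with coordinate checking, detection rate, accuracy,
    and rating-scale ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
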