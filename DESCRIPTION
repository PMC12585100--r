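Package: sleepwc
Title: Whole-Brain Wilson-Cowan Modelling of NREM Sleep Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-brain BOLD functional connectivity (FC) with a
    Wilson-Cowan neural mass network under homeostatic inhibitory plasticity,
    coupled to a Balloon-Windkessel hemodynamic stage, and fits the model to
    empirical FC across wake and NREM sleep stages by sweeping neuromodulatory
    parameter offsets (delta-G for acetylcholine acting on global coupling,
    delta-sigma for noradrenaline acting on the excitatory input-output slope),
    optionally weighted by region-specific modulation maps. Includes the
    euccorrelation fit semi-metric, hemisphere-symmetric map shuffling
    surrogates, homotopic structural-connectivity enhancement, Hierarchical
    Modular Analysis of integration and segregation, a synthetic-data generator
    for connectomes, maps and multi-subject stage datasets, and the statistical
    toolkit (Cohen's d with interpretation bins, paired t-tests with
    Benjamini-Hochberg correction, repeated-measures correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
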