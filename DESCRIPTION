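Package: efvphen
Title: Bayesian Identification of CYP2B6 Poor Metabolizers from a Single
    Efavirenz Test-Dose Concentration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether a single plasma concentration taken
    after a 600 mg oral test dose of efavirenz can identify a CYP2B6 poor
    metabolizer. Provides a calibrated population pharmacokinetic simulator
    for extensive, intermediate and poor metabolizer phenotypes (lognormal
    between-subject variability on a one-compartment oral model), an
    empirical Bayesian classifier built from binned concentration histograms
    with maximum a posteriori phenotype calls, ROC-based selection of the
    optimal sampling time, and blinded-cohort evaluation with sensitivity
    and specificity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
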