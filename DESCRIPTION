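Package: crowdmix
Title: Mixture-Model Analysis of Continuous-Report Visual Crowding Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing method-of-adjustment ("continuous report")
    visual crowding experiments in which observers reproduce the gap
    orientation of a peripheral Landolt-C target surrounded by ring
    flankers.  Provides the experiment's stimulus-design parameterisation,
    a generative observer model for simulating trial tables, circular
    statistics (wrapping, circular mean and standard deviation, percentile
    bootstrap confidence intervals), trial-wise nearest-model labelling of
    report errors into target, average and substitution reports, far-gap
    splitting and re-centering for two-gap flanker conditions, maximum
    likelihood von Mises mixture models of report errors (with an
    averaging-extended variant and a simulation grid-search estimator),
    linear slope fits, and a parameter-recovery study that validates every
    estimator on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
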