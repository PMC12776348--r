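Package: mhnet
Title: Mutual Hazard Networks for Cancer Progression Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains and analyses Mutual Hazard Networks, continuous-time
    Markov chain models of irreversible accumulation of progression events
    (e.g. driver gene mutations) in tumors, observed cross-sectionally at a
    genotype-dependent rate.  Provides exact marginal genotype likelihoods
    and analytic gradients via state space restriction, penalized
    maximum-likelihood training with cross-validated penalty selection,
    Gillespie sampling of artificial tumor histories, most-likely
    event-order reconstruction with cohort-level trajectory trees, and
    heatmap/DOT visualization exports, together with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
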