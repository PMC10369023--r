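Package: distsig
Title: Distance-Dependent Detectability and Boldness of Animal Colour Patterns
Version: 0.1.0
Authors@R: person("distsig", "maintainers", email = "distsig@example.org", role = c("aut", "cre"))
Description: Perceptual image analysis of animal colour patterns on their
    natural backgrounds under a receptor-noise-limited (RNL) model of
    non-human colour vision. From linear cone-catch image stacks the package
    applies Gaussian spatial-acuity modelling and RNL ranked filtering at a
    set of viewing distances, computes local edge intensity analysis (LEIA)
    chromatic and achromatic edge-contrast maps, and derives two focal
    pattern statistics: boldness (the abundance-weighted coefficient of
    variation of within-animal edge contrast) and detectability (the
    absolute difference between animal and background edge-contrast CoV,
    a measure of background matching). A synthetic-scene generator produces
    cone-catch cohorts with controllable pattern contrast, element size and
    coupling to chemical-defence covariates, and a statistics pipeline runs
    the downstream species comparisons (Kruskal-Wallis, Dunn post hoc,
    random-intercept mixed models with Satterthwaite df) and the
    distance-dependent correlation regression between unpalatability and
    each pattern statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    lme4,
    numDeriv,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
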