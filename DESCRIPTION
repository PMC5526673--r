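Package: quorumdyn
Title: Stochastic and Mean-Field Dynamics of Autoinducer Production in
    Quorum-Sensing Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact continuous-time stochastic simulation (Gillespie) of a
    constant-size birth-death population in which each individual carries a
    continuous autoinducer production degree in [0,1], reproduces at rate
    1 - s*p, and may adjust its degree at division by sensing the population
    average through a response function. Includes the mean-field kinetic
    ("autoinducer") equation integrated on an adaptive atom-measure
    representation, its closed-form time-dependent solutions, the bimodal
    stationary states and their existence conditions, the phase structure
    in the response probability (continuous transition at lambda = s/2,
    discontinuous jump as lambda tends to zero), and scripted experiment
    drivers for histogram evolution, absorption-time scaling, phase
    diagrams, and robustness to noisy inheritance, perception and response.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
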