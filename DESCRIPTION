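Package: eventnma
Title: Bayesian Network Meta-Analysis of Event Risks and Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian network meta-analysis models for adverse events
    reported either as the risk of at least one event (patients with an
    event out of patients randomised) or as an event rate over person-time
    exposure. Implements binomial likelihoods with logit and complementary
    log-log links, a Poisson likelihood with log link, and a
    shared-parameter model that combines both reporting formats on a common
    log-hazard scale, with fixed or random study effects and consistency or
    unrelated-mean-effects (inconsistency) structures. Provides single-arm
    baseline meta-analysis on the logit, cloglog and log-rate scales,
    residual-deviance/DIC model criticism, propagation of baseline and
    relative effects into absolute event probabilities, treatment rankings,
    expected costs and health disutilities, and a coherent trial-data
    simulator driven by a latent per-patient Poisson event process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
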