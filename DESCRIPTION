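Package: srtmcvae
Title: Deep Variational and MCMC Posterior Estimation for SRTM Kinetic
    Parameters in Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for Bayesian uncertainty quantification of
    kinetic parameters in dynamic brain PET. Generates noisy time-activity
    curves (TACs) from the simplified reference tissue model (SRTM), samples
    reference posterior distributions of (DVR, k2, R1) with a random-walk
    Metropolis-Hastings sampler, trains three conditional variational
    auto-encoder (CVAE) posterior estimators (dual-encoder, dual-decoder and
    vanilla) on simulated parameter/TAC pairs, and compares the amortized
    CVAE posteriors against the MCMC reference via relative mean/width
    differences and per-marginal Kullback-Leibler divergences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
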