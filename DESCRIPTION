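Package: nflmc
Title: Langevin Normalizing-Flow Monte Carlo Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trainable, deterministic flow-based sampler whose coupling layers
    embed Langevin-diffusion drift terms. The flow is trained with a squared
    log-density-ratio loss so that pushed-forward draws from a simple base
    distribution converge to a target (possibly unnormalized) density. Ships
    with a catalog of analytic target energies (rings, ill-conditioned and
    correlated Gaussians, rough well, Gaussian funnel, Gaussian mixtures),
    a Bayesian logistic-regression posterior with a synthetic data generator,
    Metropolis-adjusted Langevin and Hamiltonian Monte Carlo baselines, and
    sampler-quality diagnostics (autocorrelation, effective sample size,
    maximum mean discrepancy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
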