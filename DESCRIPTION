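Package: vbesim
Title: Virtual Bioequivalence Trial Simulation for Long-Acting Injectable
    Paliperidone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-integrated virtual bioequivalence (VBE) assessment for
    long-acting injectable paliperidone palmitate formulations. Simulates
    population-pharmacokinetic parallel trials from a joint one-month
    (PP1M, zero-order plus first-order depot release) and three-month
    (PP3M, dual saturable Hills depot release) structural model, applies a
    hierarchical lognormal/logit population layer with a multiplicative
    formulation-shift vector, recalibrates the shift on the slow-depot
    maximum release rate by Metropolis-Hastings MCMC from abbreviated-trial
    concentration data, and assesses bioequivalence either by two one-sided
    tests (TOST) on a large simulated trial or by the posterior-predictive
    distribution of Cmax and AUC geometric-mean ratios. Includes power and
    type-I error simulation, drug-release sensitivity ranking, and
    safe-space mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
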