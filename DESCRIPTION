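Package: hcptest
Title: Multilevel Mediation Tests for the Healthy Context Paradox in
    Cluster-Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect the healthy context paradox -- the worsening of
    outcomes among individuals who continue to experience an adverse mediator
    (for example bullying victimisation) in clusters where an intervention has
    reduced that mediator -- in cluster-randomised trials. Implements a
    baseline 2-1-1 multilevel mediation model separating within-cluster
    (individual) and between-cluster (contextual) mediator-outcome paths, a
    between-level treatment-by-mediator-mean interaction test, and a
    treatment-moderated random-slope test on the cluster-mean-centred
    mediator, with Wald comparisons of nested specifications over both fixed
    effects and variance components. Includes maximum-likelihood estimation of
    the required Gaussian linear mixed models with a joint observed-information
    parameter covariance, a synthetic two-level trial generator, and a Monte
    Carlo runner for type-I error and power of the two tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
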