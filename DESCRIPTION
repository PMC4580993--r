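Package: crossage
Title: Parental-Age Effects on Meiotic Crossover Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the effect of parental age at birth on the
    number of meiotic crossovers transmitted to a child, across multiple
    genotyped cohorts. Provides post-processing of crossover calls from
    pedigree-based detection (posterior-probability thresholding,
    double-crossover artifact filters, family-configuration classification,
    cohort exclusion rules), per-cohort linear mixed models with
    inverse-variance fixed-effects meta-analysis, Bayesian hierarchical
    normal and negative-binomial count models with empirical-Bayes priors
    fitted by MCMC with a split R-hat convergence protocol, posterior
    predictive checks, frequentist coverage and power assessment of the
    credible intervals, and a multi-cohort synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    nlme,
    metafor,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
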