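Package: gridvc
Title: Linear Mixed Models by Grid Search over Variance-Component Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Gaussian linear mixed models with multiple random effects by
    discretizing the variance-component proportions on a simplex grid. One
    Cholesky decomposition of the marginal covariance per grid vertex is
    reused across thousands of genetic markers or traits, yielding
    approximate but highly accurate REML/ML Wald and likelihood-ratio tests,
    grid-based Bayesian posteriors of variance-component proportions, and
    per-marker Bayes factors under conjugate normal-inverse-gamma priors.
    Includes accelerated ball/ring/adaptive grid-search heuristics, kinship
    matrix construction (additive, pairwise-epistatic, gene-by-environment,
    and categorical), genomic-control diagnostics, a synthetic-data
    generator for structured populations, and PLINK/delimited-text readers
    with a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
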