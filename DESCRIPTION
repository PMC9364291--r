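Package: mptsource
Title: Multinomial Processing Tree Modeling of Schema-Based Source Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the schema-based source-monitoring paradigm: the
    two-high-threshold multinomial processing-tree (MPT) model of source
    monitoring with aggregate maximum-likelihood fitting, hierarchical
    Bayesian latent-trait estimation of individual parameters with
    convergence diagnostics and posterior predictive fit statistics (T1/T2),
    Bayesian credibility intervals and parameter contrasts, the behavioral
    statistics used in metamemory experiments (mixed and within-subjects
    2x2 ANOVA with partial eta squared, paired and independent t tests with
    d_z, Goodman-Kruskal gamma correlations, Loftus-Masson within-subject
    confidence intervals, a-priori power analysis for paired designs), and a
    generative simulator of the full two-group judgment-of-source experiment
    (study, delayed judgment, restudy, and test phases).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
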