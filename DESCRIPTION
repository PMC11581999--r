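Package: twinccc
Title: Causal-Contingent-Common Twin Models for Smoking Initiation and
    Quantity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sex and birth-cohort effects on tobacco
    consumption in same-sex twin cohorts. Implements the
    causal-contingent-common (CCC) ACE twin model for a binary initiation
    phenotype (liability-threshold, age-moderated) and a contingent
    quantity phenotype, with full-information maximum likelihood over all
    observation patterns, multigroup equality constraints, likelihood-ratio
    comparison ladders, and profile-likelihood confidence intervals.  Also
    provides a three-level longitudinal mixed model of cigarette quantity
    across age (measures in individuals in pairs), descriptive surfaces
    (prevalence by sex and cohort, twin concordances and tetrachoric
    correlations), and a synthetic twin-cohort generator emulating a
    Finnish-style twin study of adults born 1880-1957, so that every stage
    is testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
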