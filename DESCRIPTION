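Package: metaepi
Title: Two-Step Meta-Epidemiological Analysis of Preclinical Meta-Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for meta-epidemiological analysis of preclinical
    systematic reviews with meta-analyses. Estimates, within each
    meta-analysis, the difference in standardized mean difference (DMSD)
    between studies at high or unclear risk of bias and studies at low
    risk via random-effects meta-regression, and pools the DMSDs across
    meta-analyses by random-effects meta-analysis. Includes effect-size
    computation (Hedges' g, Cohen's d, variance from confidence
    intervals, shared-control splitting), DerSimonian-Laird and REML
    heterogeneity estimation, cluster-robust (CR2) variance with
    Satterthwaite degrees of freedom for multi-arm dependency, a
    synthetic-data generator with known ground truth for validating the
    pipeline, and descriptive audit tabulations (counts, percentages,
    medians with quartiles) of review- and study-level methodological
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
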