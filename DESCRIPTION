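Package: mrforge
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete two-sample Mendelian randomization toolkit for GWAS
    summary statistics: reading and harmonizing exposure/outcome association
    files onto a common effect-allele frame, the instrument quality-control
    cascade (LD clumping, confounder-association filtering, Steiger
    directionality filtering, F-statistic weak-instrument filtering), six
    causal-effect estimators (Wald ratio, fixed and multiplicative
    random-effects inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode), the MR-PRESSO resampling global, outlier and
    distortion tests, heterogeneity and leave-one-out diagnostics with
    funnel and scatter data export, a binary-outcome power calculator, and a
    seeded synthetic summary-statistic generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
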