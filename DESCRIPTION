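Package: mrpipe
Title: Two-Sample Mendelian Randomisation with Sensitivity Analysis,
    Screening and Anchored Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-level Mendelian randomisation from GWAS summary
    statistics: instrument selection, allele harmonisation and strength
    metrics; Wald ratio, inverse-variance weighted (fixed, additive and
    multiplicative random effects), MR-Egger, weighted median, weighted
    mode and multivariable IVW estimators; MR-PRESSO global, outlier and
    distortion tests; Cochran's Q and I-squared heterogeneity, leave-one-out,
    single-SNP, funnel data, Steiger directionality and filtering, and
    bi-directional analysis; heritability and correlation pre-screening
    with bulk bi-directional IVW; linear-Gaussian Bayesian-network
    structure learning with genetic directional anchors (hill climbing,
    BIC, bootstrap edge support); and a synthetic two-sample GWAS
    summary-statistics generator with known ground truth covering
    pleiotropy, confounding, sample-overlap and selection-bias regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
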