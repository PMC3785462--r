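Package: haplopower
Title: Monte-Carlo Power Analysis for 2xk Case-Control Association Tables
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates a-priori and a-posteriori statistical power for
    case-control association studies over 2xk contingency tables, the
    motivating case being mtDNA haplogroup studies where k marker categories
    are compared between cases and controls of possibly unequal size. Power
    is estimated by Monte-Carlo simulation of multinomial tables, with
    p-values calibrated asymptotically, by margin-preserving permutation
    resampling, or by a Monte-Carlo Fisher exact test. A scaled
    noncentrality statistic (corrected for the number of categories)
    is calibrated against simulated power by local-linear kernel regression,
    and drives the inverse problems: minimum sample sizes under a
    control-case ratio or a fixed arm, and the minimum detectable frequency
    deviation or odds ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    KernSmooth,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
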