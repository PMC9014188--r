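Package: polyport
Title: Polygenic Score Portability and Differentiation Under Stabilizing Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of polygenic traits under Gaussian
    stabilizing selection with unlinked loci, together with analytic and
    diffusion-based predictions for the decay of shared additive genic variance
    between diverging populations. Provides idealized GWAS ascertainment schemes
    (all loci, top variance fraction, minor-allele-frequency threshold),
    polygenic-score construction and prediction-accuracy ratios across
    populations, and the Q_X / Q_ST polygenic differentiation statistics with
    their chi-square neutral null, including the behaviour of these statistics
    when both populations adapt to a shared optimum shift.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
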