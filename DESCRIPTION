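Package: cisiv
Title: Instrument Selection and Strength for cis-Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects genetic instruments for cis-Mendelian randomization from
    GWAS summary statistics and a linkage-disequilibrium (LD) reference.
    Implements standard and adjusted-R-squared-gated LD-pruning, stepwise
    conditional-and-joint selection on conditional p-values, sum-of-single-
    effects fine-mapping with credible sets, and principal-component
    instruments from the z-weighted LD matrix. Reconstructs multivariable
    effect estimates and their covariance from marginal statistics plus LD,
    computes the F-statistic, variance explained (R-squared) and adjusted
    R-squared for correlated instruments, and performs fixed-effects
    inverse-variance-weighted MR that accounts for instrument correlation,
    with eigenvalue stabilization of ill-conditioned LD matrices. A
    self-contained simulator of block-correlated genotype panels and traits
    with known variance explained supports method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
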