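Package: vqtlmap
Title: Detection of Variance-Controlling Quantitative Trait Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical tests for variability-controlling quantitative trait
    loci (vQTL): loci whose genotype predicts the variance, rather than the
    mean, of a quantitative trait. Implements classical group-based tests
    (Levene, Brown-Forsythe, Fligner-Killeen), two-stage squared-residual
    regressions (SVLM and variants), and a fully parametric double generalized
    linear model (DGLM) that jointly estimates a mean submodel and a log-linear
    dispersion submodel for Gaussian and Poisson traits. Includes Box-Cox
    scale diagnostics, hat-value screening for two-stage methods, genotype
    dosage and VCF input, genome scans with multiple-testing adjustment, and a
    Monte-Carlo benchmark of false-positive rate and power under
    gene-by-factor interaction, Gaussian-null, and Poisson-null scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    optparse
Config/testthat/edition: 3
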