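Package: trajectome
Title: Two-Timepoint Expression Trajectory Modules with Promoter H3K4me3 Integration
Version: 0.1.0
Authors@R: person("Trajectome", "Maintainers", email = "maintainers@trajectome.dev",
    role = c("aut", "cre"))
Description: A tested pipeline for longitudinal two-timepoint case/control
    RNA-seq studies with matched promoter histone-mark (H3K4me3) ChIP
    pileups. Provides moderated differential expression per timepoint with
    empirical-Bayes variance shrinkage, classification of differentially
    expressed genes into eight expression-trajectory modules, per-module
    hypergeometric gene-set over-representation, promoter-level differential
    histone-mark scoring from bedGraph pileups via a signed Poisson
    log-likelihood ratio with rank-based cross-sample comparison, and a
    module-level ANOVA with Tukey-Kramer post hoc contrasts against
    non-differential genes. Includes a negative-binomial count and Poisson
    pileup simulator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    edgeR,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
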