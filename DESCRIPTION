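Package: macmeth
Title: Paired Differential DNA Methylation Analysis of Monocyte-to-Macrophage
    Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for paired epigenome-wide analysis of DNA
    methylation remodeling during human monocyte-to-macrophage differentiation
    and activation. Implements per-CpG balanced within-donor ANOVA (the exact
    form of the donor random-intercept mixed model) with Benjamini-Hochberg
    correction and a mean-squares effect-size filter, partial-t cell-type
    attribution and gain/loss classification, consensus regulatory annotation
    (chromatin states, DNaseI hypersensitivity, promoter-capture Hi-C
    enhancers, nearest genes), Fisher-exact enrichment analyses including the
    gain-over-loss chromatin-state transition grid and TF-binding-gain tests,
    WGBS-based seed-and-extend demarcation of differentially methylated
    regions, PWM motif enrichment around differentially methylated CpGs, and
    an effect-size/DMR-size threshold sensitivity analysis. A synthetic-data
    generator with a ground-truth table emulates the study design so every
    stage runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    lme4,
    withr,
    knitr
Config/testthat/edition: 3
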