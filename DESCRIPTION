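Package: milkshelf
Title: NMR Metabolomics of Milk Storage: Spoilage Markers and Shelf-Life Kinetics
Version: 0.1.0
Authors@R:
    person("Dairy", "Metabolomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 1D 1H NMR metabolomics of pasteurized milk
    stored at multiple temperatures. Provides spectral binning (0.01 ppm),
    knowledge-base-driven multiplet quantification against an internal
    standard, untargeted Spearman/FDR screening with volcano summaries and
    PCA, Kruskal-Wallis and Steel's many-one rank tests, multifactor ANOVA
    with backward term elimination and Johnson SU normalization, and the
    kinetic models of milk spoilage: linear citric acid degradation with
    Arrhenius activation energy, and threshold-time determination with
    exponential temperature decay. Includes a synthetic-data generator that
    emulates the statistical structure of a multi-batch storage experiment
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
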