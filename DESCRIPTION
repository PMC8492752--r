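Package: limnoch4
Title: Temperature Sensitivity, Isotope Mass Balance, and Microbial
    Drivers of Lake Sediment Methane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain linking the temperature sensitivity of
    ebullitive methane flux from lake sediments to the underlying
    sediment microbiota and porewater geochemistry. Provides Arrhenius
    regression on temperature-binned bubble-trap fluxes with pairwise
    homogeneity-of-slopes tests, a stable carbon isotope mass balance
    that partitions porewater methane into generated and fugitive pools
    and classifies the dominant methanogenic pathway, community ecology
    statistics (rarefaction, Bray-Curtis, PCoA, PERMANOVA, Mantel) with
    functional-guild aggregation and qPCR absolute quantification, and
    partial least squares / multiple linear regression models that
    predict porewater methane from abiotic and microbial predictors,
    with variable importance in projection (VIP) scores. A synthetic
    core generator reproduces the statistical structure of a two-lake,
    edge-versus-middle sediment study so the full pipeline is testable
    without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
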