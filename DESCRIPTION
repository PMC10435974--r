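Package: nemafauna
Title: Soil Nematode Faunal Analysis, Metabolic Footprints and
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Indicator analysis of soil nematode communities for soil
    food-web assessment. Computes the classical nematode ecological
    indices (maturity index, plant-parasite index, Wasilewska index,
    nematode channel ratio, enrichment and structure indices), nematode
    metabolic footprints with the functional metabolic footprint rhombus
    and its faunal-profile quadrat classification, and thresholded
    Spearman co-occurrence networks with summary metrics. Ships the
    supporting statistical surface (one-way ANOVA with Duncan's multiple
    range test and letter displays, Bray-Curtis dissimilarity, principal
    coordinates analysis, permutation Mantel tests) and a synthetic-data
    generator that emulates a replicated cover-crop field design so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
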