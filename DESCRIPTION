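Package: nriskindex
Title: Block-Scale Nitrogen Loss Risk Indexing for Farms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes monthly block-scale risk of nitrogen loss to water as
    the product of nitrogen source inputs (livestock excreta and effluent,
    fertilizer, crop residues, cultivation mineralization, erosion-borne
    soil nitrogen) and modeled transport risk by leaching and surface
    runoff. Transport fractions are produced by a daily tipping-bucket soil
    water balance with a conservative nitrogen tracer, standing in for
    process-based simulator runs. Includes a mitigation layer (source
    deltas and serial multiplicative modifiers), a rank-based validation
    suite (rank regression with confidence and prediction bands,
    source-sensitivity analysis, land-use scale-factor diagnosis), and a
    seeded synthetic-data generator for farms, soils, daily climate, and
    observation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
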