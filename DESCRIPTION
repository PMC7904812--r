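Package: carbonprospect
Title: Carbon Prospecting for Avoided-Deforestation Projects in Tropical Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maps per-cell investible forest carbon under Voluntary Carbon
    Standard rules from biomass, soil and deforestation-risk rasters, prices it
    with a 30-year discounted cash-flow model, and derives viability maps,
    break-even carbon prices, price-sensitivity curves, leakage/cost/buffer
    scenario analyses, and validation statistics against issued verified carbon
    units. Includes a seeded synthetic-world generator with an independent
    scalar truth oracle so the whole pipeline is testable without external
    datasets. Rasters are exchanged as plain-text ESRI ASCII grids and vectors
    as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sp,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
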