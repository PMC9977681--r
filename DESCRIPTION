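Package: drylandtrees
Title: Tree-Level Carbon Accounting for Dryland Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates wood, foliage and root carbon of individual dryland
    trees from their crown areas using crown-area allometric power laws,
    including the large-crown splitting rule and a fixed dry-mass-to-carbon
    fraction. Aggregates per-tree carbon to per-hectare density grids and
    rainfall-zone summaries along a mean-annual-precipitation gradient,
    propagates allometric and crown-mapping uncertainty by repeated 80/20
    subsampling and quadrature, scores crown-mapping omission and commission
    errors by crown-area class, and applies deterministic image-selection
    rules for building single-coverage satellite mosaics. Ships a synthetic
    landscape and field-sample generator so the full workflow runs offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
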