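Package: soilrisk
Title: Integrated Soil Pollution Risk Assessment for Industrial and Mining Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated soil environmental risk assessment in
    industrial and mining gathering areas: per-point human health risk
    (total carcinogenic risk and hazard index) from a three-pathway
    exposure model, a weighted multi-criteria comprehensive risk index
    (CRI) for polluting factories, inverse-distance-weighted spatial
    interpolation with leave-one-out cross-validation, matrix-overlay
    integration of health risk with land use, and a fully synthetic scene
    generator (sampling designs, contaminant plume fields, factories,
    land-use rasters) with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
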