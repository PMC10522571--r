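Package: wormyield
Title: Earthworm Contributions to Crop Production from Gridded Data Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the contribution of earthworms to crop production on
    gridded (raster) data layers. Combines meta-analysis-derived multiplicative
    effect coefficients for crop type, soil pH, soil texture and nitrogen
    application rate with a continuous power-law response to earthworm
    abundance, evaluates the resulting per-cell fractional yield effect for
    each crop, converts it into counterfactual (without-earthworm) yields and
    attributable production, and aggregates results by harvested area into
    regional and global summaries. Ships a synthetic-world generator that
    emulates the statistical structure of the global input layers, including a
    known-truth mode for exact end-to-end recovery tests, plus a small
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
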