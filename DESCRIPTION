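Package: mwagg
Title: Moving-Window Aggregation of Fine-Grain Environmental Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carrying fine-grain environmental heterogeneity into
    coarse-grain ecological models. Implements moving-window data aggregation
    (MWDA): a heterogeneity metric (Shannon evenness of land-cover classes,
    variance or range of a continuous surface, or a user-supplied function) is
    evaluated in a Moore neighbourhood around every fine-resolution cell, and
    the resulting surface is then summarised within each coarse response-grain
    cell. The direct data aggregation (DDA) baseline, neutral-landscape
    simulation via spectral synthesis of fractal Brownian surfaces, weighted
    classification into land-cover classes, and a simulation study that
    measures when the scale-of-effect is recoverable by AIC-based model
    selection are included, together with plain-text (ESRI ASCII grid) raster
    input/output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
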