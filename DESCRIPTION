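Package: organoquant
Title: Organoid Brightfield Segmentation, Morphology Classification, and
    Confocal Marker Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis toolkit for intestinal organoid cultures.
    Segments organoid objects from projected brightfield z-stacks,
    classifies each organoid as spheroid or budding with a compact
    convolutional network (plus an interpretable shape-feature fallback)
    and a manual-correction cycle, and quantifies confocal marker signal
    per organoid or region of interest: tuft-cell spot counting,
    positive-pixel fractions, ROI intensity ratios, and treatment-level
    summaries with two-sample tests. A deterministic synthetic scene
    generator provides complete ground truth so every stage of the
    pipeline can be validated without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
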