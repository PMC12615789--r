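Package: nfmap
Title: Desk-Scale Natural Forest Probability Mapping with a Multi-Modal
    Temporal-Spatial Vision Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating probabilistic natural-forest
    maps from multi-temporal optical satellite imagery at desk scale. Provides
    a seeded synthetic-scene generator with class-specific phenology and
    texture, rule-based fusion of heterogeneous label sources into 9-class
    training masks, a multi-modal temporal-spatial vision transformer
    (MTSViT) for per-pixel semantic segmentation with ensemble training,
    overlapping-window inference with inverse-distance weighted stitching,
    probability quantization and tile input/output, temperature-scaling
    calibration with adaptive-binning reliability assessment, and
    design-based stratified accuracy estimation (overall, user's and
    producer's accuracy with standard errors) including threshold sweeps and
    high-confidence commission/omission error analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
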