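Package: germVision
Title: Automated Counting of Striga Seed Germination in Filter Assay Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for automated quantification of Striga hermonthica seed
    germination in glass-fibre filter assay images. Provides a synthetic
    assay-image simulator with exact ground-truth annotations, readers and
    writers for Pascal-VOC (LabelImg) and Darknet-style bounding-box
    annotation dialects, anchor-box derivation by IoU-distance K-means,
    decoding of grid-and-anchor detector output with objectness filtering
    and class-wise non-maximum suppression, a classical morphological
    reference detector, per-image seed and radicle-onset counting with
    germination percentages, overlay rendering, translation-only image-pair
    stitching, and model-selection machinery (objectness-threshold and
    checkpoint sweeps driven by the average germination-difference metric,
    per-class bias, and counting-error histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    withr,
    xml2,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Visualization, Classification
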