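Package: cycifer
Title: Cyclic Immunofluorescence Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of tissue-based cyclic immunofluorescence
    (t-CyCIF) experiments, in which a specimen is imaged over successive
    four-channel stain/image/bleach rounds and the rounds are assembled into
    a high-plex single-cell dataset. Provides a synthetic multiplexed-tissue
    image generator with known ground truth; illumination-shading estimation
    and correction, rolling-ball background subtraction, grid stitching by
    phase correlation, and rigid cross-cycle registration; watershed nuclear
    segmentation with centripetal cytoplasm expansion and per-cell intensity
    quantification; cycle quality control (fluorophore-inactivation folds,
    tissue-integrity curves, dynamic range, distribution-overlap scores);
    Gaussian-mixture phenotype clustering with model selection and t-SNE
    embedding; and spatial analysis (field-wise Shannon entropy, marker
    gating, k-nearest-neighbour density and co-occurrence maps, bootstrapped
    counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rtsne,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
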