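Package: hippocount
Title: Cell Counting, Debris Detection and Morphometry for Confocal
    Hippocampal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Layered blob detection, cross-layer cell linking,
    neuronal-debris classification and pyramidal-layer morphometry for
    three-channel (NeuN/GFAP/IBA1) confocal z-stacks of hippocampal
    regions of interest. Per-layer segmentation uses Gaussian smoothing,
    local-mean adaptive thresholding and morphological refinement; blobs
    are linked across layers by area overlap and classified as cells by
    their Feret (longest) diagonal. Includes a calibrated synthetic-stack
    generator with exported ground truth, Bland-Altman method-agreement
    statistics with an interchangeability rule, and the small defined
    statistics of a pentylenetetrazole-kindling study (brain-to-plasma
    ratios, novel-object discrimination index, Racine-scale kindling
    bookkeeping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
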