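Package: spheroquant
Title: Pixel-Based Quantification of Multicellular Spheroid Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation-free quantification of cell invasion from
    multicellular spheroids into 3D matrices from paired nuclear-stain
    fluorescence images. Binarizes maximum-projection images with a global
    threshold, segments the initial (Day 0) spheroid boundary as a closed
    polygon, aligns it onto the final (Day 2) image by centroid overlap, and
    computes per-pixel radial distances and angles past the boundary, the
    area change, the radial area moment of inertia as an integrative
    invasiveness metric, and PCA-based invasion directionality. Includes a
    synthetic fixture generator with analytically known metrics, MAD-based
    outlier flagging, batch consolidation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2,
    optparse
Config/testthat/edition: 3
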