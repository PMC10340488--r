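Package: wbcseg
Title: Ensemble White Blood Cell Nuclei Segmentation and Logit Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments white blood cell (leukocyte) nuclei in stained blood-smear
    micrographs by fusing two complementary segmenters: a handcrafted pipeline
    that applies color constancy, extracts the CMYK Magenta and HSV Saturation
    channels, combines them by a Hadamard product, and refines an Otsu
    binarization with morphological operations; and a small U-Net trained with
    the Mish activation and the Unified Focal Loss. The two masks are merged by
    a pixelwise logical AND followed by an area opening. Also provides the six
    standard pixelwise segmentation metrics (accuracy, precision, recall,
    specificity, Dice, IoU), a cluster-separability analysis of classifier
    logits in PCA space (the Dist/SD ratio), and deterministic generators of
    synthetic blood smears with ground-truth masks and of Gaussian logit clouds
    so that every stage is testable without external image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
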