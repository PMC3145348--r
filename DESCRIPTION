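Package: assayScreen
Title: Feature Screening for Image-Based Assay Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the "screening" approach to high-content assay
    development: a large library of per-cell features (intensity, shape,
    Haralick texture, channel correlation, radial intensity distribution,
    speckle counts) is measured over nuclear, cytoplasmic and whole-cell
    compartments of two-channel fluorescence images, derived ratio and
    classified-fraction features are added, everything is aggregated per
    image and screened with Z-prime and V-factor assay-quality statistics
    against plate-map control and dose metadata to select the best single
    readout, with held-out train/test validation. Includes illumination
    correction by median-filtered average, top-hat speckle enhancement with
    per-object thresholding, seeded geodesic cell propagation, and a
    deterministic synthetic image generator emulating cytoplasm-to-nucleus
    translocation and speckle-formation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Rcpp,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
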