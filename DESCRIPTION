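Package: reedmap
Title: National-Scale Reedbed Mapping from Multi-Temporal Multispectral Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a national
    reedbed (Phragmites australis) mapping workflow for Sentinel-2-like
    multispectral imagery. Covers the complete chain from raw multi-temporal
    13-band passes through dark-object subtraction, random-forest cloud
    masking, integer co-registration and seasonal median compositing, to a
    spectral-index feature stack, a dual random-forest classifier fused by
    per-pixel minimum probability, kappa-optimal thresholding, terrain
    masking, hectare-scale aggregation, and a stratified validation design
    with commission/omission-corrected extent estimation. A synthetic scene
    generator with class-specific seasonal phenology, rare-class patches,
    clouds, cloud shadows, mis-registration and per-pass reflectance error
    stands in for the satellite archive so that every stage can be exercised
    and verified without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    randomForest,
    EBImage,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
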