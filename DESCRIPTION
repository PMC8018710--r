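Package: histopam
Title: Passive Cavitation Mapping and Targeting Accuracy Metrics for
    Robot-Assisted Histotripsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale computational pipeline for assessing the targeting
    accuracy of image-guided, robot-positioned histotripsy. Provides linear
    (Rayleigh-Sommerfeld) focal-field simulation for an elliptic focused
    source with derived -6 dB focal widths and predicted ablation footprint;
    passive acoustic mapping of cavitation emissions from multi-element RF
    channel data with the robust Capon beamformer (and a delay-and-sum
    baseline); treatment-path planning by arc-length waypoint interpolation
    and hexagonal packing; segmentation-based accuracy metrics (Otsu masks,
    centroid targeting error, Dice similarity, Hausdorff distance, fiducial
    co-registration); and a synthetic-data generator that produces RF channel
    data, vessel/clot phantom images and liquefaction masks with known ground
    truth for closed-loop validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pracma, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
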