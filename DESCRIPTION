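Package: optotrack
Title: Multi-Animal Centroid Tracking and Optogenetic Stimulus Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline tracking of many small animals (fly larvae, adult
    flies, zebrafish) in arena videos: median background modelling,
    thresholded foreground segmentation, size-gated connected-component
    detection, and identity-preserving multi-object tracking that uses
    temporal mean area and primary-axis length to keep identities through
    collisions. Includes an optogenetics analysis layer (stimulus waveform
    generation, timestamped state-log handling with two-clock drift
    correction, per-epoch displacement and velocity statistics with paired
    Wilcoxon comparison, quadratic illuminance-to-irradiance calibration)
    and a synthetic arena-video generator with exact ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    matrixStats,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
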