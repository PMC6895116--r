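Package: nashscoreR
Title: Automated Pathologist-Like Scoring of NAFLD/NASH Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tile-based deep-learning scoring of liver histopathology for
    non-alcoholic fatty liver disease (NAFLD) and steatohepatitis (NASH).
    Whole-slide images are cut into two-scale non-overlapping tile grids,
    classified per histological feature (ballooning, inflammation, steatosis,
    fibrosis) by small convolutional networks with a global-average-pooling
    softmax head, tile softmax confidences are ignore-filtered, renormalized
    and aggregated into one continuous score per liver, and a Monte Carlo
    threshold search maps the continuous scores to discrete Kleiner-style
    pathologist scores. Includes class-activation-map visualization, the full
    agreement-metric suite (MAE, Cohen's kappa, weighted precision/recall/F1),
    and a synthetic trichrome-like tile and cohort generator so that every
    stage is testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
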