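Package: preybout
Title: Kinematic Classification of Larval Zebrafish Hunting Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for head-fixed larval zebrafish prey-capture
    experiments: digitizes the tail from high-speed video into ordered midline
    points, converts traces into kinematic time series, segments swim bouts with
    a threshold on the normalized smoothed derivative of the tail bend angle,
    computes sixteen per-bout kinematic parameters, and classifies bouts as prey
    capture or spontaneous swims with a radial-basis-function support vector
    machine under fivefold stratified cross-validation. Includes prey-capture
    scoring and stimulus tuning curves, a calcium-imaging module (sliding
    percentile delta-F-over-F baselines, condition ratio maps, ROI responses,
    gated two-group statistics), and a seeded synthetic-data generator that
    renders ground-truth tail videos and fluorescence movies so the whole
    pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    e1071,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
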