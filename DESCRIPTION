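Package: flarekit
Title: Quantitative Analysis of Turn-Taking Aggressive Displays in Fighting Fish
Version: 0.1.0
Authors@R:
    person("Flarekit", "Developers", email = "flarekit@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying visually driven turn-taking aggressive
    displays in Siamese fighting fish (Betta splendens) from pose-tracking
    output. Cleans keypoint tables, extracts smoothed kinematic features
    (orientation, speed, operculum geometry, tail geometry, elevation),
    classifies opercular flaring with a dilated temporal convolutional
    network, tests stimulus-locked synchronization of flaring to a looped
    animation with a circular-shift resampling null, computes point-biserial
    flare-feature correlations with shuffle controls, peri-event time
    histograms around flare bout onsets and offsets, exponential
    engagement-decay (persistence) curves, and dyadic behavioral-state
    transition graphs with spectral layouts. Includes a synthetic dyad and
    animation-response simulator so the full pipeline can be exercised
    without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
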