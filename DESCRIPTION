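Package: flysnb
Title: Quantification of Drosophila Social Network Behavior from Arena Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying social network behavior
    (SNB) in groups of Drosophila freely moving in a circular arena: an
    agent-based simulator of fly group trajectories with clustering and
    dispersing behavioral regimes, a synthetic video renderer, a dark-blob
    tracker (arena calibration, subpixel detection, optimal-assignment
    identity linking, gap filling), the group phenotypes used to screen
    natural variation in sociality (social distance, walking speed, group
    centroid velocity, quarter dynamics, travel distance), and cohort-level
    analytics (line ranking, extreme-line selection, tie-safe Spearman rank
    correlation with permutation p-values, and plasticity contrasts between
    rearing or injury conditions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
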