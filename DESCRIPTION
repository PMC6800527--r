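Package: divetrack
Title: Three-Dimensional Scoring of Zebrafish Novel Tank Diving Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional behavioral phenotyping of zebrafish
    in the novel tank diving test. Synchronizes top- and front-view 2D
    trajectory streams by their shared x coordinate, fuses them into 3D
    tracks, and scores a nine-measure ethogram (speed, acceleration and
    angular-speed averages and 90th-percentile peak averages, freezing,
    wall following, and time in the top half of the water column) per
    1-minute time bin. Provides correlation-matrix PCA with eigenvalue
    retention and varimax rotation, split-plot repeated-measures ANOVA with
    Dunnett many-to-one contrasts, and a false-positive/false-negative
    ledger comparing conclusions drawn from 2D projections against 3D
    ground truth. Includes a stochastic swim simulator that generates
    synthetic cohorts with condition- and time-bin-dependent locomotion,
    freezing, wall attraction, and depth preference for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
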