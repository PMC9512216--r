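Package: plumetrack
Title: Video-Based Measurement of Exhaled Aerosol Plume Impulse Dispersion
Version: 0.1.0
Authors@R:
    person("plumetrack", "developers", email = "plumetrack@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the impulse dispersion of exhaled
    aerosol-proxy vapor clouds from multi-view video recordings, as used in
    infection-control studies of speaking and wind-instrument playing.
    Provides frame-stack input with negative conversion and polygon
    exclusion masking, global-threshold cloud segmentation with
    small-component removal, scale-bar pixel-to-metre calibration,
    directional extent tracking from a mouth origin with the task-end time
    convention, moving-median plus cubic-spline temporal smoothing,
    cross-subject summary tables at fixed timepoints with a +/- 0.1 m
    comparison markup, and long-term average spectrum (LTAS) comparison of
    audio recordings.  A synthetic two-view plume video and tone-audio
    generator with analytic ground truth makes the whole pipeline testable
    without studio footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
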