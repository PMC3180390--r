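Package: dtws
Title: Balanced Dynamic Time Warping with Time-Shift Significance for
    Developmental Expression Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Aligns two noisy, non-uniformly sampled gene-expression time
    series (for example the same gene's developmental trajectory in two
    species) with a balanced, end-unanchored dynamic time warping and
    reports a time-shift estimate at every interpolated time point of the
    query series. Trajectories are smoothed with cubic smoothing splines and
    resampled on uniform grids before alignment; the warping selects exactly
    as many reference columns as there are query points, so the remaining
    reference columns are omitted and the series ends need not align.
    Includes a simulation-based significance test for the per-point shifts
    with false-positive-rate calibration of the per-gene significant-point
    count, benchmark generators that inject known constant or variable
    heterochrony into sine, linear and quadratic signals, and an
    application-layer pipeline for gene screening, direction-of-heterochrony
    classification and shift-profile clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
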