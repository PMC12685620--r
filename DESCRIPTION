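Package: apextrack
Title: Markerless Diaphragm-Based Tumor Tracking for Rotational Dual-kV Imaging
Version: 0.1.0
Authors@R:
    person("Apextrack", "Developers", email = "apextrack@example.org",
           role = c("aut", "cre"))
Description: Tools for markerless real-time tumor tracking during volumetric
    modulated arc therapy with two orthogonal rotating kV imagers. Implements
    the stereo projection geometry (forward projection, ray back-projection,
    skew-ray midpoint triangulation, epipolar constraints), an
    epipolar-constrained normalized cross-correlation matcher that localizes
    the diaphragm apex against angle-indexed templates, phase-dependent
    offset-vector models mapping the apex to the tumor, a quadratic
    external-surrogate correlation model for prediction, and percentile-based
    tracking-error statistics. A deterministic synthetic phantom generates
    respiratory signals, coupled diaphragm/tumor/fiducial trajectories and
    rendered projection frames for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
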