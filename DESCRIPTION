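Package: conetraj
Title: Two-Stage 3D Cone k-Space Trajectory Design and Dynamic Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design tools for center-out two-stage parametric 3D cone k-space
    trajectories with 3D golden-ratio shot ordering, time-optimal gradient
    waveform synthesis under amplitude and slew-rate limits, flexible
    spatiotemporal binning for combined angiographic and perfusion arterial
    spin labeling acquisitions, trajectory quality metrics (point spread
    function width, pseudo-replica effective SNR, signal-to-aliasing power
    ratio), and image reconstruction by density-compensated adjoint NUFFT or
    locally-low-rank regularized iteration. Includes synthetic digital
    phantoms (vessel, perfusion compartment, resolution comb) and a multi-coil
    forward acquisition model for end-to-end simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
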