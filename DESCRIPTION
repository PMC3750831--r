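Package: tomogate
Title: Respiratory-Gated Sparse-View Phase-Contrast CT Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and reconstruction toolkit for in-line (propagation
    based) phase-contrast computed tomography of breathing subjects. Provides
    a breathing-phantom acquisition simulator with Fresnel edge enhancement,
    retrospective respiratory gating from AP/MP inter-frame statistics,
    scale-space keypoint (SIFT-style) alignment with RANSAC similarity
    estimation, angular-spectrum Fresnel propagation with error-reduction
    phase retrieval, a Siddon ray-driven parallel-beam projector, filtered
    back projection, and a compressed-sensing reconstruction that minimises
    image total variation with ART (Kaczmarz) data-consistency sweeps, for
    sparse-view slice reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
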