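Package: holocell
Title: Lens-Free Holographic Reconstruction of Cells in Suspension
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Physics-based reconstruction of quantitative phase (optical path
    difference) and absorption images of cells in suspension from lens-free
    in-line holograms. Implements a Fresnel-propagation forward model with a
    partial-coherence kernel, a total-variation regularized inverse solver
    minimized by nonlinear conjugate gradient, a synthetic sphere-cell phantom
    simulator with Poisson sensor noise, a fully-convolutional phase-unwrapping
    network trained on simulated reconstructions, and the three-step
    alternation pipeline (first reconstruction, network unwrapping, final
    reconstruction) together with quantitative evaluation tools (PSNR,
    per-cell refractive-index recovery, regression summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
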