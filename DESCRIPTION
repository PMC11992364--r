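Package: pherograd
Title: Reaction-Diffusion Modeling and Inference for Optogenetic Yeast
    Pheromone Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models steady-state alpha-factor pheromone gradients generated
    by surface-attached yeast cells under a gel, as in optogenetic
    half-domain assays: closed-form trigonometric-integral concentration
    profiles for surface production with cell uptake and for a
    perfect-sink (Bar1 protease) geometry, a sparse finite-difference
    steady-state solver for the underlying two-dimensional
    reaction-diffusion problem, Hill dose-response composition for
    gene-expression and morphological readouts, a synthetic single-cell
    table generator emulating segmentation output, and a joint
    least-squares inference pipeline that recovers the gradient decay
    length, far-field concentration and morphological Hill coefficient
    from binned two-channel single-cell data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
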