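Package: rhombosim
Title: Stochastic Multiscale Simulation of Zebrafish Hindbrain Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid discrete-continuum simulator of rhombomere formation and
    boundary sharpening in the zebrafish hindbrain (r2-r6, 11-14 hpf). Couples
    stochastic convection-reaction-diffusion dynamics of two morphogens
    (retinoic acid and FGF) on a convergently extending rectangular domain with
    per-cell stochastic gene regulation (hoxb1a, krox20, vhnf1, irx3) and
    subcellular-element cell mechanics with krox20-selective sorting. Includes
    the boundary-location / sharpness-index / dislocated-cell quantification,
    reduced one-dimensional and sorting-only models, and runners for
    convergence-schedule comparisons, time-window ablations and random-parameter
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
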