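Package: corowave
Title: One-Dimensional Pulse-Wave Modelling of the Coronary Arterial Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear one-dimensional pulse-wave simulation of the large
    coronary arteries on a measured vessel-segment network. Outflow boundaries
    are closed by structured-tree vascular-bed impedances (Womersley
    frequency-domain flow in self-similar binary trees) with a myocardial
    feedback pressure driven by a time-varying elastance ventricle model.
    Includes wave-intensity analysis with six-wave segmentation of the
    coronary cycle, and scenario runners for arterial stiffening, vascular
    rarefaction, feedback-pressure sweeps and geometric scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
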