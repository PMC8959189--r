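Package: pymtme
Title: Data-Driven ODE Modeling of the PyMT Breast-Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a data-driven ordinary-differential-equation model of
    the cell and cytokine interaction network in PyMT mouse breast tumors.
    Ships the published three-mouse, four-timepoint immune-deconvolution time
    courses, non-dimensionalizes them by per-variable maxima, rearranges the
    fifteen coupled ODEs into a system linear in the 57 interaction rates,
    and estimates those rates by bound-constrained linear least squares.
    Includes trajectory simulation, direct-differential (forward) sensitivity
    analysis averaged over a parameter neighborhood with a sparse quadrature
    grid, single-parameter bifurcation scans of the day-42 cancer load, a
    synthetic pseudo-mouse study generator, and ggplot2 visualisations with
    broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
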