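Package: mschaeffer
Title: Mitchell-Schaeffer Cardiac Action Potential Models Robust to
    Pacemaker Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements the two-variable Mitchell-Schaeffer (MS) cardiac
    ionic model and a modified variant (mMS) in which the outward
    (repolarising) current is gated by the complement of the recovery
    variable, removing the spurious pacemaker (auto-oscillatory) behaviour
    the original model can exhibit.  Provides closed-form nullcline and
    phase-plane analysis, analytic leading-order action-potential-duration
    (APD) restitution, s1-s2 and dynamic pacing protocols with alternans
    (2:2) and block (2:1) classification, a parameter-grid robustness sweep
    classifying pacemaker activity across tens of thousands of parameter
    sets, and a 2D monodomain tissue simulator with cross-field (spiral
    wave) stimulation.  Single-cell dynamics are integrated with a backward
    Euler scheme with Newton iterations implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
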