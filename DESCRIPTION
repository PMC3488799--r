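Package: ctcfit
Title: Genetic-Algorithm Fitting of Mouse Action-Potential Models and the
    In Silico Cell-Type Transforming Clamp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rapid genetic-algorithm tuning of a neonatal-mouse
    ventricular action-potential model to a recorded (or synthesized) action
    potential, and for simulating the cell-type transforming clamp (CTC): the
    closed-loop dynamic-clamp variant that injects the difference between a
    human recipient model's and a mouse target-canceling model's membrane
    currents so that a mouse myocyte expresses a human-like action potential.
    Includes the modified Pandit neonatal-mouse and reduced ten Tusscher-
    Panfilov human ventricular models as forward-Euler ODE systems, action-
    potential morphology metrics (APD at several repolarization levels,
    sum-of-squared-differences fitting error), the nine-member APD80 template
    suite used by the baseline model-selection approach, a pseudo-cell
    generator emulating beat-to-beat variability, and a command-line
    workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
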