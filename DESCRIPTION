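Package: whipneck
Title: Efficient Planar Head-Neck Multibody Model for Rear-Impact Whiplash Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward dynamics of a planar (sagittal) head-neck multibody chain
    (T1, C7..C1, head) with nonlinear torsional joint springs and linear dampers,
    driven by a prescribed T1 base motion such as a rear-impact sled pulse.
    Includes recovery of occipital-condyle loads by inverse dynamics, the HIC36
    and Nkm injury criteria, a sequential RMS-minimisation parameter
    identification pipeline with 25 percent sensitivity screening, and a
    synthetic reference-kinematics generator so the full identification
    workflow can be exercised from known ground-truth parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
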