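Package: cardioinfer
Title: Inference of Ventricular Activation Properties from ECG and
    Epicardial Activation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for personalising the ventricular activation sequence of
    a biventricular heart model from non-invasive electrophysiological data.
    Activation is simulated with an anisotropic graph-Eikonal model (orthotropic
    myocardial conduction plus a fast isotropic endocardial layer) solved by
    multi-source Dijkstra propagation, and 12-lead QRS complexes are derived
    with a pseudo-ECG current-source model.  Earliest-activation root nodes
    (discrete) and four conduction speeds (continuous) are inferred jointly by
    sequential Monte Carlo approximate Bayesian computation, using a
    slope-and-band constrained dynamic time warping discrepancy for ECG targets
    and root-mean-square error for epicardial activation time maps.  Includes a
    synthetic torso-biventricular geometry generator, a virtual-subject cohort
    builder with controlled noise contamination, aggregation of posterior
    populations (median speeds, k-means root-node centroids), evaluation
    metrics, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
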