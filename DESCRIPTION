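Package: bridgefibre
Title: Force Balance in the Metaphase Spindle from Bridging-Fibre Elastic Rod Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring forces at the spindle pole and kinetochore in
    metaphase from measured spindle geometry, using an Euler-Bernoulli
    elastic-rod model in which a bridging fibre of overlap microtubules links
    the sister k-fibres at a junction near each kinetochore. Includes a
    fixed-step midpoint (RK2) integrator for the three-rod boundary-value
    problem, an inverse solver for the pole force, kinetochore tension and
    junction position, sweeps of the pole force against bridging-fibre
    thickness, quantification utilities for tubulin line-scan intensity
    profiles (background subtraction, peak areas, bridging-to-k-fibre
    microtubule ratios) and for kinetochore tracks from laser-ablation assays
    (perpendicular displacement, interkinetochore relaxation, sister tilt,
    stub length), and a calibrated synthetic-data generator that emulates the
    measured population statistics so that the full pipeline is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
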