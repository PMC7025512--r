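Package: vacoupler
Title: Closed-Loop Multiscale Simulation of Ventricular-Arterial Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop multiscale simulator of the cardiopulmonary
    circulation. An eight-compartment lumped-parameter circulation (valves,
    vessel resistances, venous compliances, atrial time-varying elastance) is
    coupled bidirectionally to finite-element models of a biventricular unit
    (Guccione transversely isotropic passive myocardium with an active
    sarcomere contraction model, cavity volumes enforced by Lagrange
    multipliers whose converged values are the cavity pressures) and of
    membrane arteries (constrained-mixture wall energy with an elastin matrix,
    four collagen fiber families and circumferential smooth muscle).
    Idealized geometries (truncated-ellipsoid biventricle, spherical shells,
    cylinders, bifurcations) are generated programmatically with rule-based
    transmural fiber fields.  Includes scenario experiments for pulmonary
    arterial hypertension progression (collagen accumulation, reduced right
    ventricular contractility, raised distal pulmonary resistance),
    periodicity detection, hemodynamic metrics, and tidy/ggplot2 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
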