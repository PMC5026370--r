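Package: chemrelax
Title: Chemical Relaxation Kinetics of Induced-Fit and
    Conformational-Selection Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing chemical relaxation experiments on
    protein-ligand binding with a conformational change.  Implements
    closed-form near-equilibrium relaxation rates for the induced-fit and
    conformational-selection three-state schemes at arbitrary total protein
    and ligand concentrations (beyond the pseudo-first-order approximation),
    mass-action simulation of relaxation curves, multi-exponential fitting
    with small-sample corrected AIC model selection, and mechanism inference
    from k_obs versus ligand-concentration data via constrained weighted
    least squares and Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
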