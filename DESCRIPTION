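Package: csmsim
Title: Cancer Stem Cell Population Dynamics with Stochastic Parameters and
    Drug Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a four-variable nonlinear
    dynamical model of heterogeneous tumor growth under the cancer stem cell
    hypothesis. The model couples cancer stem cells, differentiated cancer
    cells and two chemical activators through a mitosis/plasticity feedback
    loop. The package computes the model's fixed points with existence
    conditions and Jacobian-eigenvalue stability classification, extends the
    system with Wiener (white-noise) evolution of selected rate parameters
    and quantifies trajectory-bundle widths by unbinned Gaussian maximum
    likelihood, and implements a one-compartment pharmacokinetic model with
    periodic dosing together with four pharmacodynamic therapy couplings
    (cytotoxic, cytostatic, anti-plasticity and combined
    differentiation-plus-cytotoxic). Every published parameter regime ships
    as a named, runnable scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
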