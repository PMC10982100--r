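Package: neuralpk
Title: Low-Dimensional Neural Ordinary Differential Equations for
    Single-Dose Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacokinetically principled neural ordinary differential
    equations (NODEs) for single-dose concentration-time data. The
    right-hand sides are small one-hidden-layer networks with separated
    concentration- and time-dependence, a weight restriction that makes
    the time-dependence vanish, and optional known mechanistic terms
    (first-order elimination or absorption). Includes mechanistic
    compartment-model oracles (one- and two-compartment IV bolus, oral
    absorption with transit compartments, IV infusion, target-mediated
    drug disposition) for synthetic data generation, pooled full-batch
    training with Adam and a cyclic learning rate via exact
    backpropagation through a Runge-Kutta discretization, and
    derivative-versus-state diagnostics for overfitting, interpolation,
    and extrapolation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
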