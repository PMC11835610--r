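Package: wardflow
Title: Compartmental Dynamics of Hospital In-Patient Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a four-compartment dynamical model of acute medical
    patient flow through a hospital: emergency department, Covid ward,
    general medical ward and intensive care unit, coupled by saturating
    (Holling type II) transfer terms. Provides the model right-hand side
    and analytic Jacobian in two documented variants, closed-form and
    numerically located equilibria with residual verification, local
    stability classification by eigenvalues and by the Routh-Hurwitz
    criterion on the characteristic polynomial, stiffness-aware forward
    simulation with cumulative discharge and mortality series, limit-cycle
    period estimation from peak detection, one-parameter equilibrium sweeps
    with Hopf-crossing detection, and two-parameter stability heat maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
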