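Package: rwame
Title: Random Walk Approximation for Master Equations on State Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Stationary solutions of non-linear one-step master equations on
    finite state graphs with a conserved particle number. Implements the
    Random Walk Approximation (RWA) -- a multinomial-like ansatz built from
    the density-dependent null eigenvector of the graph Laplacian -- together
    with the benchmark methods it is usually compared against: exact master
    equation solutions (sparse null-space solve and adaptive Runge-Kutta
    integration), Gillespie sampling, the System Size Expansion (linear noise
    approximation) via the Lyapunov equation, and the linearized multinomial
    approximation. Ships two built-in models, a one-parameter threshold toy
    model and the dual phosphorylation/dephosphorylation cycle under standard
    quasi-steady-state Michaelis-Menten kinetics, plus bifurcation
    diagnostics and distribution comparison metrics (l1, Jensen-Shannon).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
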