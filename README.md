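# rwame — Random Walk Approximation for master equations on state graphs

Mesoscopic biological systems — phosphorylation cycles, gene regulatory
circuits, signalling networks — are often well described as `N` identical
particles hopping on a graph of `M` states, with per-particle rates
`π_ij(x)` (from state `j` to `i`) that depend on the density vector
`x = n/N`. With conserved `N`, the occupation probabilities obey a one-step
master equation whose stationary solution has no closed form once the rates
are density-dependent — precisely the regime where bistability and critical
slowing down appear.

`rwame` implements the **Random Walk Approximation (RWA)** of that
stationary solution, together with every benchmark it is usually compared
against. The RWA keeps the multinomial shape of the exactly solvable linear
(constant-rate) case,

    ρ(n) = C(N) · N! · ∏_k  p_k(n/N)^{n_k} / n_k! ,

but re-evaluates the occupation probabilities `p(x)` — the null eigenvector
of the graph Laplacian `L(x) = diag(d(x)) − π(x)` — at each lattice state's
*own* density. That makes the approximation global (it captures tails and
contains bifurcations by itself) and reduces the whole problem to an
eigenvector computation. For constant rates it is exact. Its ℓ1 error
against the true stationary solution is of order `‖∂p/∂x‖` at the stable
fixed point, independent of `N`.

Included solvers and diagnostics, all producing the same
`lattice_distribution` container over the conserved-`N` simplex lattice:

* `rwa_distribution()` — the RWA, evaluated in log space, with `log C(N)`
  and the Jacobian-norm error scale; `mode_check()` flags spurious modes.
* `stationary_nullspace()` / `integrate_to_stationarity()` — exact solution
  by sparse null-space solve or adaptive Dormand–Prince RK5(4).
* `gillespie_sample()` — continuous-time stochastic simulation.
* `sse_distribution()` — System Size Expansion (linear-noise) Gaussians via
  the Lyapunov equation; `multinomial_approximation()` — rates frozen at
  the fixed point.
* `find_critical_points()`, `bifurcation_scan()` — self-consistent states
  `p(x*) = x*`, stability from the eigenvalues of `∂p/∂x` (stable iff all
  real parts < 1), and bifurcation location by continuation + bisection.
* `l1_distance()`, `js_divergence()`, `js_distance()`,
  `covariance_error()`, `compare_methods()`, `run_sweep()` — comparison
  metrics and experiment orchestration.

Two models ship with the package: a one-parameter three-state threshold
model (`toy_model(alpha)`, bistable above `α_c ≈ 0.878`) and the dual
phosphorylation/dephosphorylation cycle under standard quasi-steady-state
Michaelis–Menten kinetics (`pdpc_model()`, bistable above `v2 = 2.5` with
the default constants).

## Worked example

The dual phosphorylation cycle in its bistable regime:

```r
library(rwame)
model <- pdpc_model(pdpc_params(v2 = 3.04))   # bistable regime
N <- 205

exact <- stationary_nullspace(build_generator(model, N))
rwa   <- rwa_distribution(model, N)
sse   <- sse_distribution(model, N)

exact
#> <lattice_distribution> on N = 205, M = 3 (21321 states); max p = 0.001266 at n = (9, 99, 97)
rwa
#> <rwa_result> log C(N) = -2.43166, |dp/dx| at x* = 1.431
#> <lattice_distribution> on N = 205, M = 3 (21321 states); max p = 0.0007389 at n = (6, 89, 110)

find_critical_points(model)
#> [[1]]
#> <critical_point> x* = (0.048097, 0.490196, 0.461707)  stable  max Re(eig) = 0.857895
#> [[2]]
#> <critical_point> x* = (0.189055, 0.621891, 0.189055)  unstable  max Re(eig) = 1.07649
#> [[3]]
#> <critical_point> x* = (0.461707, 0.490196, 0.048097)  stable  max Re(eig) = 0.857895

cat(sprintf("JS error (%%): RWA %.1f, SSE %.1f\n",
            100 * js_distance(rwa$dist, exact),
            100 * js_distance(sse, exact)))
#> JS error (%): RWA 28.2, SSE 27.0

mode_check(model, rwa)[1:2, ]
#>    n_1 n_2 n_3         prob    label
#> 2    6  89 110 0.0007388995 spurious
#> 13 110  89   6 0.0007388995 spurious
```

Reading the output: the exact stationary law peaks at `1.27e-3` on the two
mirror wells; the RWA reproduces the bistable structure globally with a
Jensen–Shannon error (base-2, root scale) of ~28%, on par with the
artificially mixed two-Gaussian SSE — and `mode_check` honestly reports
that past the bifurcation the RWA's peaks are displaced from the
deterministic fixed points (the method's documented limitation; its
eigenvalue criterion `max Re(eig) > 1` at the symmetric point is exactly
the bifurcation signature).

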