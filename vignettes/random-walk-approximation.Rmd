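---
title: "Approximating stationary distributions of non-linear master equations on graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximating stationary distributions of non-linear master equations on graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwame)
```

## The problem

Many mesoscopic biological systems — gene regulatory circuits, signalling
cascades, phosphorylation cycles — are naturally described as $N$ identical
particles hopping on a graph of $M$ states, where the per-particle transition
rates $\pi_{ij}(\vec{x})$ from state $j$ to state $i$ depend on the current
density vector $\vec{x} = \vec{n}/N$. With a conserved particle number
($|\vec{n}| = N$) the probability $\rho(\vec{n}, t)$ of each occupation vector
obeys a one-step master equation (ME): exactly one particle moves per event,
so transitions connect states $\vec{n}$ and $\vec{n} - e_j + e_i$ with rate
$\pi_{ij}(\vec{n}/N)\, n_j$ (the package rescales time by $N$, which leaves
stationary distributions untouched and makes relaxation rates order one).

For constant rates the stationary solution is the multinomial distribution
built from the null eigenvector $\vec{p}$ of the graph Laplacian
$L = \mathrm{diag}(d) - \pi$, $d_k = \sum_i \pi_{ik}$. For density-dependent
rates no closed solution exists in general, and the interesting phenomena —
bistability, critical slowing down — live exactly in that regime.

## The Random Walk Approximation

The package's core method keeps the multinomial *shape* but re-evaluates the
occupation probabilities at each lattice state's own density:

$$\rho_{\mathrm{RWA}}(\vec{n}) \;=\; C(N)\, N! \prod_{k=1}^{M}
  \frac{p_k(\vec{n}/N)^{\,n_k}}{n_k!},$$

where $\vec{p}(\vec{x})$ is the Laplacian null eigenvector at density
$\vec{x}$ and $C(N)$ normalizes over the lattice. Because $\vec{p}$ follows
the state, the ansatz is *global*: it captures tails and can contain a
bifurcation without being told where the stable states are. For constant
rates it reduces to the exact multinomial.

Three diagnostics accompany the distribution:

* **Self-consistency.** Deterministic steady states solve
  $\vec{p}(\vec{x}^*) = \vec{x}^*$; `find_critical_points()` locates them by
  multi-start Newton iteration and classifies stability from the eigenvalues
  of $\partial p/\partial x$ (stable iff all real parts are $< 1$).
* **Error scale.** The $\ell_1$ distance between the RWA and the exact
  stationary solution is of the order of the spectral norm of
  $\partial p / \partial x$ at the stable critical point, *independently of*
  $N$ (`jacobian_norm_bound()`, `me_residual_l1()`).
* **Modes.** `mode_check()` finds the lattice local maxima under the
  process's own moves and flags any that do not sit within $2/N$ of a
  self-consistent critical point: after a bifurcation the RWA may acquire
  such spurious peaks, and the package reports rather than repairs them.

A bifurcation of the underlying dynamics is signalled by an eigenvalue of
$\partial p/\partial x$ crossing 1 (equivalently a null eigenvalue of
$\delta_{ik} - \partial p_i/\partial x_k$); `bifurcation_scan()` tracks a
critical point along a parameter grid by numerical continuation and refines
the crossing by bisection.

## Benchmark methods

Everything the RWA is usually compared against is built in, all returning
the same `lattice_distribution` container:

* **Exact null-space solve** (`stationary_nullspace()`): the sparse one-step
  generator $W$ is assembled over the full lattice and its stationary vector
  is obtained by replacing one row with the all-ones row (the left null
  vector of a conservative generator) and solving the resulting nonsingular
  sparse system by LU factorization. Residuals $\lVert W\rho \rVert_1$ are
  verified below $10^{-10}$; typical value $\sim 10^{-13}$.
* **Runge–Kutta integration** (`integrate_to_stationarity()`): an embedded
  Dormand–Prince RK5(4) stepper with adaptive step-size control, run until
  the stationarity residual drops below threshold. The stepper is written
  directly on sparse matrix-vector products; it is cross-validated in the
  test suite against both the null-space solve and an independent
  general-purpose integrator (deSolve's `ode45`) on a small lattice.
* **Gillespie sampling** (`gillespie_sample()`): continuous-time simulation
  with propensities $\pi_{ij}(\vec{n}/N) n_j$ updated after every event and
  time-weighted occupancy counting after burn-in.
* **System Size Expansion** (`sse_distribution()`): the linear-noise Gaussian
  at each stable critical point, with covariance from the Lyapunov equation
  $\bar{A}\Sigma + \Sigma\bar{A}^{\mathsf T} = D^*$ in reduced coordinates.
* **Frozen multinomial** (`multinomial_approximation()`): the zero-order
  linearization — the plain multinomial with $\vec{p}$ frozen at
  $\vec{p}(\vec{x}^*)$.

## Built-in models

**Toy threshold model** (`toy_model(alpha)`). A three-state chain
$A\!-\!B\!-\!C$ with outward rates 1 and inward rates throttled by
$\theta(x) = 1 - \alpha + \alpha(1 - x)^2$: a crowded outer state slows its
own drain toward the middle. One parameter, exact $A\leftrightarrow C$
symmetry, linear at $\alpha = 0$. The symmetric state loses stability at
$\alpha_c \approx 0.878$ (located by the spectral criterion; the printed
closed-form condition for this model is typographically ambiguous in its
source, so the generic spectral test is authoritative here and the bracket
$(0.8, 0.9)$ is asserted in the tests).

**Dual phosphorylation cycle** (`pdpc_model()`). The classic two-cycle
enzymatic motif: unphosphorylated, singly and doubly phosphorylated substrate
with four Michaelis–Menten reactions reduced under the standard
quasi-steady-state approximation. With the symmetric defaults
($k_1{=}k_4{=}0.1$, $k_2{=}k_3{=}1$, $v_1{=}v_4{=}1$, $v_3{=}v_2$) the single
velocity $v_2$ controls a pitchfork bifurcation at exactly
$v_2 = v_1(1+k_2)/(1-2k_1) = 2.5$. The symmetric critical state
$\vec{x}^*_1 \propto (k_1 v_2,\, k_2 v_1,\, k_1 v_2)$ exists always; above
threshold two mirror states appear with
$x_B = k_2 v_1/(v_2 - v_1)$ and outer coordinates solving
$x^2 - x\,\frac{v_2 - v_1(1+k_2)}{v_2-v_1} +
\left(\frac{k_1 v_2}{v_2-v_1}\right)^2 = 0$. The constant term of this
quadratic was rederived here from the root-sum/discriminant structure (the
discriminant vanishes exactly at threshold, and the roots zero the
deterministic flow to $10^{-17}$ numerically — both checked in the tests).

## Worked example

```{r example, eval = FALSE}
model <- pdpc_model(pdpc_params(v2 = 3.04))  # bistable regime
N <- 205

exact <- stationary_nullspace(build_generator(model, N))
rwa   <- rwa_distribution(model, N)
sse   <- sse_distribution(model, N)

max(exact$prob)      # ~1.27e-3
max(rwa$dist$prob)   # ~7.39e-4
100 * js_distance(rwa$dist, exact)  # ~28% Jensen-Shannon error
mode_check(model, rwa)              # two consistent mirror modes
```

## Numerical choices

* **Log-space products.** All multinomial-like weights go through `lgamma`;
  $N!$ overflows double precision at $N = 171$ while $N = 205$ is a standard
  problem size here. Conventions: $0\log 0 = 0$; a state occupying a
  category with $p_k = 0$ gets probability zero, not an error.
* **Simplex-tangent derivatives.** $\vec{p}$ exists only on the simplex, so
  all derivatives are central differences (step $h = 10^{-6}$) along
  $e_i - e_{\mathrm{ref}}$, with the middle (B) state as the reference for
  three-state models and the last state otherwise. The reference row of the
  returned Jacobian is zero; its nonzero spectrum equals the reduced
  Jacobian's, so stability tests are unaffected by the convention.
* **Null vector.** Three-state chains use the closed form
  $\vec p \propto (\pi_{AB}\pi_{BC},\, \pi_{BA}\pi_{BC},\, \pi_{CB}\pi_{BA})$;
  the general path solves the dense eigenproblem, flips sign if needed,
  clips negatives below $10^{-12}$ and renormalizes (Perron–Frobenius
  guarantees a nonnegative null vector for connected graphs). Residual
  $\lVert L p\rVert_\infty < 10^{-10}$ is enforced, and degenerate null
  spaces (disconnected graphs) raise an error.
* **Root finding.** Fixed points of $x \mapsto p(x)$ are found in reduced
  coordinates (eliminating the reference state) by damped Newton with
  finite-difference Jacobians, from a deterministic grid of starts plus
  seeded random ones; duplicates merge when within $10^{-6}$ in the max
  norm; converged points must satisfy
  $\lVert p(x^*) - x^*\rVert_1 < 10^{-9}$.
* **Stability threshold.** Real part $< 1 - 10^{-9}$ counts as stable;
  within $10^{-9}$ of 1 is flagged marginal (the underlying criterion is a
  strict inequality).
* **Reduced SSE coordinates.** The density constraint makes the full
  $3\times 3$ Lyapunov problem singular, so drift and diffusion are reduced
  to $(x_A, x_C)$ — the coordinates in which the explicit three-state ME is
  written, and in which the chain's diffusion matrix is diagonal. The sign
  convention of $\bar A$ is verified *at every call* against the numerical
  Jacobian of the reduced flow; a mismatch aborts loudly. The Gaussian
  prefactor is irrelevant because every mixture is renormalized over the
  lattice; bistable mixtures use equal weights, justified by the exact
  $A\leftrightarrow C$ symmetry of both shipped models (an attribute carries
  the components so asymmetric use cases can reweight by hand).
* **$C(N)$.** Computed by exact summation over the lattice rather than any
  perturbative estimate: the lattices used here (up to $\sim 8\times 10^4$
  states) make exactness cheap, and it removes one approximation layer. Its
  logarithm is exposed as `log_norm` and stays $O(1)$ in $N$ for the toy
  model below the bifurcation (checked empirically in the tests).
* **Integrator tolerances.** The stationarity residual the RK stepper can
  reach scales with its local error tolerance (stiff modes hold
  $\lVert W\rho\rVert_1$ at a floor once the state is essentially
  stationary), so the defaults are tight (`rtol = 1e-12`, `atol = 1e-16`),
  which makes the $10^{-10}$ stop threshold reachable; a stall detector
  stops the integration if the residual plateaus above the threshold
  instead of exhausting the step budget. Trajectory-oriented runs (the
  relaxation experiments) pass `rtol = 1e-8`, which is cheaper and
  plenty for a distance trace.
* **Relaxation fits.** `relaxation_rate()` fits $\log$ distance against time
  on the final decade of decay *above a noise floor* (default $10^{-7}$):
  the integrator's tolerance leaves an $\ell_1$ distance floor (order
  $10^{-8}$ at `rtol = 1e-8`), and fitting into that floor severely biases
  the rate toward zero. The floor is an explicit argument.
* **Long bistable relaxations.** Deep in the bistable regime the slowest
  mode is nearly degenerate with zero, and integrating to a $10^{-10}$
  residual is disproportionately expensive. `integrate_to_stationarity()`
  therefore accepts a finite `t_max` (returning `converged = FALSE` with a
  warning) and can measure its distance trace against a caller-supplied
  reference — in practice the null-space solution — so relaxation rates can
  be fitted over a fixed horizon. The relaxation-contrast test integrates
  the toy model at $N = 200$ to $t = 50$ ($\alpha = 0.4$) and $t = 120$
  ($\alpha = 0.9$); these horizons give three-plus clean decades of decay
  for the fast case and a full decade for the slow one.

## What the built-in experiments do and do not show

The test suite and the reproduction script run the two shipped models at the
study's own sizes ($N$ up to 205, lattices up to 21,321 states; the
$C(N)$-boundedness check goes to $N = 400$). These are real
three-species systems, not toys scaled beyond recognition — but they are
*symmetric chains* with smooth rates. Passing tests therefore demonstrate
the method's behavior for low-dimensional, symmetric, locally interacting
networks; they do not probe asymmetric mixtures (where the equal-weight SSE
convention would be wrong), graphs with direct $A\leftrightarrow C$ edges
(handled by the generic eigensolve path, exercised only on random linear
models), many-species networks (the per-state eigenproblem scales as
$O(M^3)$ and the lattice combinatorially), or rates with discontinuities.

## Known limitations

* The RWA is mathematically controlled only below the bifurcation; beyond
  it the package detects and reports spurious modes but offers no repair.
* The equal-weight mixture convention for bistable SSE/multinomial
  approximations relies on exchange symmetry.
* `find_critical_points()` is a multi-start local method: it cannot certify
  that *all* fixed points were found, only that analytics and numerics agree
  on the shipped models.
* Gillespie occupancy uses a plain R event loop (~20 µs/event); budget
  accordingly for long runs.
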