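#' Three-state threshold toy model
#'
#' A minimal one-parameter model on the chain A - B - C: transitions toward
#' the outer states have unit rate, while the rates back toward B are
#' throttled by the occupancy of the departing state through the threshold
#' function `theta(x) = 1 - alpha + alpha (1 - x)^2`. At `alpha = 0` the
#' model is linear (all rates 1); as `alpha -> 1` a crowded outer state
#' shuts down its B-ward rate, and beyond a critical `alpha` in (0.8, 0.9)
#' the symmetric state loses stability and the system becomes bistable.
#'
#' @param alpha Control parameter in `[0, 1]`.
#' @return A [state_graph_model()].
#' @export
toy_model <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("parameter error: alpha must be a scalar in [0, 1]", call. = FALSE)
  }
  theta <- function(z) 1 - alpha + alpha * (1 - z)^2
  rates <- function(x) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- 1           # B -> A
    m[2, 1] <- theta(x[1]) # A -> B, throttled by the A occupancy
    m[3, 2] <- 1           # B -> C
    m[2, 3] <- theta(x[3]) # C -> B, throttled by the C occupancy
    m
  }
  state_graph_model(3, rates, params = list(alpha = alpha), name = "toy")
}

#' Critical alpha of the toy model
#'
#' The control-parameter value at which the symmetric self-consistent state
#' loses stability, located by the generic spectral criterion: bisection on
#' the largest eigenvalue of the reduced Jacobian of `p` at the tracked
#' symmetric critical point (crossing of 1). The value lies in (0.8, 0.9).
#'
#' @param lower,upper Bracket for the scan grid.
#' @param tol Bisection tolerance.
#' @return The critical `alpha`.
#' @export
toy_critical_alpha <- function(lower = 0.5, upper = 1, tol = 1e-6) {
  scan <- bifurcation_scan(function(a) toy_model(a),
                           seq(lower, upper, length.out = 11), tol = tol)
  attr(scan, "crossing")
}

#' Parameters of the dual phosphorylation cycle
#'
#' Michaelis-Menten constants `k1..k4` (dimensionless concentrations) and
#' maximal rate velocities `v1..v4` of the four enzymatic reactions of the
#' dual phosphorylation/dephosphorylation cycle under the standard
#' quasi-steady-state approximation. The defaults are the reduced symmetric
#' parameter set `k1 = k4 = 0.1`, `k2 = k3 = 1`, `v1 = v4 = 1`, `v3 = v2`,
#' leaving `v2` as the single control parameter (bifurcation at
#' `v2 = 2.5`).
#'
#' @param v2 Control parameter (maximal velocity of the second
#'   phosphorylation).
#' @param k1,k2,k3,k4,v1,v3,v4 Remaining kinetic constants.
#' @return Named list of validated parameters.
#' @export
pdpc_params <- function(v2 = 1.82, k1 = 0.1, k2 = 1, k3 = 1, k4 = 0.1,
                        v1 = 1, v3 = v2, v4 = 1) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
            v1 = v1, v2 = v2, v3 = v3, v4 = v4)
  if (any(unlist(p) <= 0)) {
    stop("parameter error: all kinetic constants must be positive",
         call. = FALSE)
  }
  p
}

#' Dual phosphorylation/dephosphorylation cycle model (sQSSA)
#'
#' Three-species model of a double phosphorylation cycle: `x_A`, `x_B`,
#' `x_C` are the unphosphorylated, singly and doubly phosphorylated
#' substrate densities. Each of the four reactions follows Michaelis-Menten
#' kinetics reduced under the standard quasi-steady-state approximation,
#' giving the density-dependent rates
#' \deqn{\pi_{AB} = k_4 v_2 / (k_4 k_2 + k_4 x_B + k_2 x_C)}
#' \deqn{\pi_{BA} = k_3 v_1 / (k_1 k_3 + k_1 x_B + k_3 x_A)}
#' \deqn{\pi_{CB} = k_1 v_3 / (k_1 k_3 + k_1 x_B + k_3 x_A)}
#' \deqn{\pi_{BC} = k_2 v_4 / (k_2 k_4 + k_4 x_B + k_2 x_C)}
#' With the default symmetric parameters the model is invariant under the
#' A <-> C exchange, monostable for `v2 < 2.5` and bistable above.
#'
#' @param params A [pdpc_params()] list (or arguments passed to it via
#'   `...`).
#' @param ... Convenience: forwarded to [pdpc_params()] when `params` is
#'   missing.
#' @return A [state_graph_model()].
#' @export
pdpc_model <- function(params = pdpc_params(...), ...) {
  p <- params
  rates <- function(x) {
    dAC <- p$k4 * p$k2 + p$k4 * x[2] + p$k2 * x[3]
    dAB <- p$k1 * p$k3 + p$k1 * x[2] + p$k3 * x[1]
    m <- matrix(0, 3, 3)
    m[1, 2] <- p$k4 * p$v2 / dAC  # pi_AB
    m[2, 1] <- p$k3 * p$v1 / dAB  # pi_BA
    m[3, 2] <- p$k1 * p$v3 / dAB  # pi_CB
    m[2, 3] <- p$k2 * p$v4 / dAC  # pi_BC
    m
  }
  state_graph_model(3, rates, params = p, name = "pdpc")
}

#' Analytic critical points of the dual phosphorylation cycle
#'
#' The symmetric critical state
#' `x1* = (k1 v2, k2 v1, k1 v2) / (k2 v1 + 2 k1 v2)`
#' exists for every parameter choice. When the bistability conditions
#' `(v2 - v1 (1 + k2))^2 >= (2 k1 v2)^2`, `v2 >= v1`, and
#' `v2 >= v1 (1 + k2)` all hold, two additional mirror-symmetric states
#' appear with `x_B = k2 v1 / (v2 - v1)` and outer coordinates given by the
#' roots of
#' `x^2 - x [v2 - v1 (1 + k2)] / (v2 - v1) + [k1 v2 / (v2 - v1)]^2 = 0`.
#' A discriminant within `1e-12` of zero is treated as the bifurcation point
#' itself (double root).
#'
#' @param params A [pdpc_params()] list.
#' @return List of density vectors (1 or 3 critical states); each zeroes the
#'   deterministic flow to below `1e-9`.
#' @export
pdpc_critical_points <- function(params = pdpc_params()) {
  p <- params
  den <- p$k2 * p$v1 + 2 * p$k1 * p$v2
  pts <- list(c(p$k1 * p$v2, p$k2 * p$v1, p$k1 * p$v2) / den)
  cond <- (p$v2 - p$v1 * (1 + p$k2))^2 >= (2 * p$k1 * p$v2)^2 &&
    p$v2 >= p$v1 && p$v2 >= p$v1 * (1 + p$k2)
  if (cond) {
    s <- (p$v2 - p$v1 * (1 + p$k2)) / (p$v2 - p$v1)
    q <- (p$k1 * p$v2 / (p$v2 - p$v1))^2
    disc <- s^2 - 4 * q
    if (abs(disc) <= 1e-12) disc <- 0  # double root: the bifurcation itself
    xb <- p$k2 * p$v1 / (p$v2 - p$v1)
    xp <- (s + sqrt(disc)) / 2
    xm <- (s - sqrt(disc)) / 2
    pts <- c(pts, list(c(xp, xb, xm), c(xm, xb, xp)))
  }
  pts
}

#' Bistability threshold of the dual phosphorylation cycle
#'
#' The smallest `v2` at which the three bistability conditions hold
#' simultaneously. The binding inequality is
#' `v2 - v1 (1 + k2) = 2 k1 v2`, giving the closed form
#' `v2 = v1 (1 + k2) / (1 - 2 k1)` (requires `k1 < 1/2`; otherwise no
#' threshold exists and `Inf` is returned with a warning). With the default
#' parameters the threshold is exactly 2.5. The same crossing is located by
#' the spectral [bifurcation_scan()], which serves as the independent
#' cross-check in the test suite.
#'
#' @param params A [pdpc_params()] list; only the parameters other than
#'   `v2` are used.
#' @return The threshold value of `v2`.
#' @export
pdpc_bistability_threshold <- function(params = pdpc_params()) {
  p <- params
  if (p$k1 >= 0.5) {
    warning("no bistability threshold exists for k1 >= 1/2")
    return(Inf)
  }
  p$v1 * (1 + p$k2) / (1 - 2 * p$k1)
}

#' Look up a built-in model by name
#'
#' Registry used by the configuration reader and the command-line tool.
#'
#' @param name `"toy"` or `"pdpc"`.
#' @param params Named list of parameters (`alpha` for the toy model;
#'   [pdpc_params()] arguments for the cycle model).
#' @return A [state_graph_model()].
#' @export
builtin_model <- function(name, params = list()) {
  switch(name,
    toy = toy_model(if (length(params)) params$alpha else 0),
    pdpc = pdpc_model(do.call(pdpc_params, params)),
    stop("unknown model '", name, "'; built-ins are 'toy' and 'pdpc'",
         call. = FALSE)
  )
}
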