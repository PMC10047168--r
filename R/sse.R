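#' Reduced drift and diffusion matrices at a critical point
#'
#' Linear-noise (system size) expansion ingredients at a stable critical
#' point `x*`. The drift matrix is
#' `Abar_ij = L*_ij + sum_k (dL_ik/dx_j)* x*_k`
#' with derivatives taken along simplex-tangent directions, reduced to the
#' independent coordinates (all states except the reference coordinate, see
#' [jacobian_p()]); in the package's sign convention the reduced `-Abar`
#' equals the Jacobian of the reduced deterministic flow, and this identity
#' is verified numerically at every call (the computation aborts loudly on a
#' sign error). The diffusion matrix is
#' `D_ij = (1/N) [ delta_ij sum_k (pi_ik x_k + pi_ki x_i) - (pi_ij x_j + pi_ji x_i) ]`
#' evaluated at `x*` and reduced likewise.
#'
#' @param model A [state_graph_model()].
#' @param x_star A `"critical_point"` (from [find_critical_points()]) or a
#'   plain density vector at which the flow vanishes.
#' @param N Particle number carried by the `1/N` factor of the diffusion
#'   matrix (default 1: the density-scale matrix; divide later).
#' @param h Finite-difference step for the Laplacian derivatives.
#' @return List with `A` (reduced drift, eigenvalues with positive real
#'   part at a stable point), `D` (reduced diffusion, symmetric positive
#'   semidefinite), and `free` (the indices of the reduced coordinates).
#' @export
drift_and_diffusion <- function(model, x_star, N = 1, h = 1e-6) {
  x <- if (inherits(x_star, "critical_point")) x_star$x_star else x_star
  M <- model$M
  assert_density(x, M)
  if (inherits(x_star, "critical_point") && !x_star$stable) {
    stop("unstable-expansion-point error: SSE requires a stable critical point",
         call. = FALSE)
  }
  ref <- reference_state(M)
  free <- setdiff(seq_len(M), ref)
  Lstar <- laplacian(model, x)

  # Abar_ij = L*_ij + sum_k dL_ik/dx_j x*_k, constrained derivative along
  # e_j - e_ref; reduction subtracts the L*_{i,ref} column (chain rule of
  # the eliminated coordinate).
  Abar <- matrix(0, M, M)
  for (j in seq_len(M)) {
    if (j == ref) next
    d <- numeric(M)
    d[j] <- h
    d[ref] <- -h
    dL <- (laplacian(model, x + d) - laplacian(model, x - d)) / (2 * h)
    Abar[, j] <- Lstar[, j] + as.numeric(dL %*% x)
  }
  A_red <- Abar[free, free, drop = FALSE] -
    matrix(Lstar[free, ref], length(free), length(free))

  # loud sign-convention check: -A_red must be the Jacobian of the reduced
  # deterministic flow
  Jnum <- matrix(0, length(free), length(free))
  for (jj in seq_along(free)) {
    d <- numeric(M)
    d[free[jj]] <- h
    d[ref] <- -h
    Jnum[, jj] <- (deterministic_rhs(model, x + d) -
                     deterministic_rhs(model, x - d))[free] / (2 * h)
  }
  if (max(abs(-A_red - Jnum)) > 1e-4 * max(1, max(abs(Jnum)))) {
    stop("internal sign-convention failure: reduced -Abar does not match the flow Jacobian",
         call. = FALSE)
  }

  m <- rate_matrix(model, x)
  D <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      D[i, j] <- if (i == j) {
        sum(m[i, ] * x + m[, i] * x[i])
      } else {
        -(m[i, j] * x[j] + m[j, i] * x[i])
      }
    }
  }
  D_red <- D[free, free, drop = FALSE] / N

  list(A = A_red, D = D_red, free = free)
}

#' Solve the continuous Lyapunov equation
#'
#' Solves `A S + S A' = D` for the stationary covariance `S` by Kronecker
#' vectorization (the reduced systems here are tiny, so the direct dense
#' solve is exact). `A` must be stable in the positive-real-part convention
#' used by the expansion; at a bifurcation `A` acquires a zero eigenvalue
#' and the equation is singular.
#'
#' @param A Reduced drift matrix.
#' @param D Reduced diffusion matrix (symmetric positive semidefinite).
#' @return Symmetric covariance matrix with residual Frobenius norm below
#'   `1e-10` relative to the data scale.
#' @export
solve_lyapunov <- function(A, D) {
  d <- nrow(A)
  stopifnot(ncol(A) == d, all(dim(D) == d))
  if (min(Re(eigen(A, only.values = TRUE)$values)) < 1e-12) {
    stop("singular-Lyapunov error: drift matrix has an eigenvalue at or below 0 (at a bifurcation the expansion breaks down)",
         call. = FALSE)
  }
  K <- kronecker(diag(d), A) + kronecker(A, diag(d))
  S <- matrix(solve(K, as.numeric(D)), d, d)
  S <- (S + t(S)) / 2
  resid <- norm(A %*% S + S %*% t(A) - D, "F")
  if (resid > 1e-10 * max(1, norm(D, "F"))) {
    stop("Lyapunov residual ", format(resid), " too large", call. = FALSE)
  }
  S
}

#' System Size Expansion (linear noise) stationary approximation
#'
#' For each stable critical point the Gaussian of the linear-noise
#' approximation is built in reduced density coordinates: covariance from
#' the Lyapunov equation (carrying the `1/N` of the diffusion matrix), mean
#' at the critical point. In a bistable regime the components are mixed with
#' equal weights -- justified by the exact exchange symmetry of the shipped
#' models -- and the mixture is evaluated at every lattice density and
#' renormalized over the lattice (the continuous Gaussian prefactor is
#' irrelevant after lattice normalization).
#'
#' @param model A [state_graph_model()].
#' @param N Particle number.
#' @param critical_points Optional list of critical points (or density
#'   vectors) to expand around; defaults to all stable points found by
#'   [find_critical_points()].
#' @return A [lattice_distribution()]; attribute `"components"` holds one
#'   `list(mean, sigma, weight)` per Gaussian.
#' @export
sse_distribution <- function(model, N, critical_points = NULL) {
  lat <- simplex_lattice(N, model$M)
  cps <- sse_expansion_points(model, critical_points)
  dens <- lat$states / N
  w <- numeric(lat$size)
  comps <- list()
  for (x in cps) {
    dd <- drift_and_diffusion(model, x, N = N)
    Sig <- solve_lyapunov(dd$A, dd$D)
    Si <- solve(Sig)
    dx <- dens[, dd$free, drop = FALSE] -
      matrix(x[dd$free], lat$size, length(dd$free), byrow = TRUE)
    q <- rowSums((dx %*% Si) * dx)
    w <- w + exp(-q / 2) / length(cps)
    comps[[length(comps) + 1]] <- list(mean = x, sigma = Sig,
                                       weight = 1 / length(cps))
  }
  dist <- lattice_distribution(lat, w)
  attr(dist, "components") <- comps
  dist
}

#' Multinomial approximation with rates frozen at the critical point
#'
#' The zero-order linearization benchmark: the occupation probabilities are
#' frozen at `p(x*)` for each stable critical point and the plain linear
#' multinomial stationary solution is used, mixed with equal weights in a
#' multistable regime and normalized over the lattice. For a linear model
#' this is the exact stationary solution; for non-linear models it is a
#' purely local approximation.
#'
#' @inheritParams sse_distribution
#' @return A [lattice_distribution()].
#' @export
multinomial_approximation <- function(model, N, critical_points = NULL) {
  lat <- simplex_lattice(N, model$M)
  cps <- sse_expansion_points(model, critical_points)
  w <- numeric(lat$size)
  lgN <- lgamma(N + 1)
  lgfact <- rowSums(lgamma(lat$states + 1))
  for (x in cps) {
    p <- null_eigenvector(model, x)
    lp <- ifelse(p > 0, log(p), -Inf)
    lw <- lgN + as.numeric(lat$states %*% ifelse(is.finite(lp), lp, 0)) - lgfact
    # states using a zero-probability category get weight zero
    if (any(!is.finite(lp))) {
      bad <- lat$states[, !is.finite(lp), drop = FALSE]
      lw[rowSums(bad) > 0] <- -Inf
    }
    w <- w + exp(lw - log_sum_exp(lw)) / length(cps)
  }
  lattice_distribution(lat, w)
}

# Shared resolution of the expansion points: stable critical points unless
# explicitly supplied.
sse_expansion_points <- function(model, critical_points) {
  if (is.null(critical_points)) {
    cps <- Filter(function(cp) cp$stable, find_critical_points(model))
    if (!length(cps)) {
      stop("no stable critical point exists for this model", call. = FALSE)
    }
    lapply(cps, function(cp) cp$x_star)
  } else {
    lapply(critical_points, function(cp) {
      if (inherits(cp, "critical_point")) cp$x_star else as.numeric(cp)
    })
  }
}
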