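#' Define a state-graph model with density-dependent transition rates
#'
#' A state-graph model is the single object consumed by every solver in the
#' package: `M` chemical species (graph nodes) and a rate function mapping a
#' density vector `x` on the simplex to an `M x M` nonnegative matrix whose
#' entry `(i, j)` is the per-particle transition rate from state `j` to state
#' `i` (units of inverse rescaled time). Rates must depend on the densities
#' `x = n / N` only, never on the particle number `N` itself; this is what
#' makes the thermodynamic structure of the process independent of system
#' size.
#'
#' @param M Positive integer, the number of states.
#' @param rates Function of a length-`M` density vector returning an
#'   `M x M` nonnegative matrix; diagonal entries are ignored (treated as 0).
#' @param params Named list of model parameters (kept for provenance and
#'   reporting; the `rates` closure should already capture them).
#' @param name Label used in printed output and result tables.
#' @return An object of class `"state_graph_model"`.
#' @examples
#' two_state <- state_graph_model(2, function(x) matrix(c(0, 1, 2, 0), 2, 2),
#'                                name = "two-state")
#' null_eigenvector(two_state, c(0.5, 0.5))  # (2/3, 1/3)
#' @export
state_graph_model <- function(M, rates, params = list(), name = "model") {
  stopifnot(is.numeric(M), length(M) == 1, M >= 2, M == round(M))
  stopifnot(is.function(rates))
  model <- structure(
    list(M = as.integer(M), rates = rates, params = params, name = name),
    class = "state_graph_model"
  )
  # probe once at the barycenter so malformed models fail at construction
  rate_matrix(model, rep(1 / M, M))
  model
}

#' @export
print.state_graph_model <- function(x, ...) {
  cat(sprintf("<state_graph_model> '%s': M = %d states\n", x$name, x$M))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# Evaluate and validate the rate matrix at a density x.
rate_matrix <- function(model, x) {
  m <- model$rates(as.numeric(x))
  if (!is.matrix(m) || any(dim(m) != model$M)) {
    stop("invalid model: rates() must return an M x M matrix", call. = FALSE)
  }
  diag(m) <- 0
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("invalid model: rates() returned a negative or non-finite rate",
         call. = FALSE)
  }
  m
}

# Check that x is a density vector on the simplex.
assert_density <- function(x, M, tol = 1e-9) {
  stopifnot(length(x) == M)
  if (any(x < -tol) || abs(sum(x) - 1) > max(tol, 1e-12)) {
    stop("x is not on the probability simplex", call. = FALSE)
  }
  invisible(x)
}

#' Graph Laplacian of a model at a given density
#'
#' Returns `L = diag(d) - pi(x)` with `d_k` the total out-rate of node `k`
#' (the column sum of the rate matrix). Every column of `L` sums to zero,
#' which expresses conservation of probability flux.
#'
#' @param model A [state_graph_model()].
#' @param x Density vector on the simplex.
#' @return An `M x M` matrix with zero column sums.
#' @export
laplacian <- function(model, x) {
  assert_density(x, model$M)
  m <- rate_matrix(model, x)
  L <- -m
  diag(L) <- colSums(m)
  L
}

#' Null eigenvector of the graph Laplacian
#'
#' The normalized nonnegative right null vector `p(x)` of `L(x)`: the
#' single-particle stationary occupation probabilities of the random walk
#' frozen at density `x`. For three-state chain models (no direct 1<->3
#' transitions) the closed form
#' `p = (pi_12 pi_23, pi_21 pi_23, pi_32 pi_21) / Z` is used; otherwise a
#' dense eigensolve picks the eigenvalue of smallest magnitude. Existence and
#' uniqueness follow from Perron-Frobenius when the rate graph at `x` is
#' strongly connected.
#'
#' @inheritParams laplacian
#' @return Density vector `p` with `L %*% p ~ 0`, `p >= 0`, `sum(p) == 1`.
#' @export
null_eigenvector <- function(model, x) {
  assert_density(x, model$M)
  m <- rate_matrix(model, x)
  p <- null_vector_of_rates(m)
  resid <- max(abs((diag(colSums(m)) - m) %*% p))
  if (resid > 1e-10) {
    stop("null-vector residual ", format(resid), " exceeds 1e-10", call. = FALSE)
  }
  p
}

# Core computation on a validated rate matrix (no re-validation; used in the
# per-lattice-state hot loop of the RWA).
null_vector_of_rates <- function(m) {
  M <- nrow(m)
  if (M == 3 && m[1, 3] == 0 && m[3, 1] == 0) {
    # chain topology 1 - 2 - 3: closed form from pairwise balance
    den <- m[1, 2] * m[2, 3] + m[3, 2] * m[2, 1] + m[2, 1] * m[2, 3]
    if (den <= 0) stop("disconnected graph: degenerate null space", call. = FALSE)
    return(c(m[1, 2] * m[2, 3], m[2, 1] * m[2, 3], m[3, 2] * m[2, 1]) / den)
  }
  L <- -m
  diag(L) <- colSums(m)
  e <- eigen(L)
  lam <- abs(e$values)
  scale <- max(lam, 1)
  if (sum(lam < 1e-9 * scale) > 1) {
    stop("disconnected graph: Laplacian null space has dimension > 1",
         call. = FALSE)
  }
  v <- Re(e$vectors[, which.min(lam)])
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-12 * max(abs(v))) {
    stop("disconnected graph: null vector changes sign", call. = FALSE)
  }
  v <- pmax(v, 0)
  v / sum(v)
}

#' Deterministic (mean-field) dynamics of the densities
#'
#' Right-hand side of `dx/dt = -L(x) x`, the average dynamics of the master
#' equation in rescaled time. Components always sum to zero, so the flow
#' preserves the simplex.
#'
#' @inheritParams laplacian
#' @return Length-`M` vector summing to 0.
#' @export
deterministic_rhs <- function(model, x) {
  assert_density(x, model$M)
  as.numeric(-laplacian(model, x) %*% x)
}

# Reference coordinate eliminated on the simplex: the middle (B) state for
# three-state models, the last state otherwise. Derivatives and reduced
# coordinates are taken along the tangent directions e_i - e_ref.
reference_state <- function(M) if (M == 3) 2L else M

#' Jacobian of the Laplacian null eigenvector on the simplex
#'
#' Central finite differences of `p(x)` along simplex-tangent directions:
#' coordinate `i` is incremented and the reference coordinate (see Details)
#' decremented by the same step, so every probe stays on the simplex. Entry
#' `(i, k)` of the returned matrix is `dp_k / dx_i`; the row belonging to the
#' reference coordinate is identically zero (its tangent direction is null),
#' so the nonzero spectrum equals that of the reduced
#' `(M-1) x (M-1)` Jacobian used for stability and bifurcation tests.
#'
#' @details The reference coordinate is the middle state for `M = 3` (the
#' models shipped with the package eliminate the B species) and the last
#' state otherwise. Rows of the underlying Jacobian satisfy
#' `sum_k dp_k/dx_i = 0` because `p` is normalized.
#'
#' @inheritParams laplacian
#' @param h Finite-difference step (default `1e-6`).
#' @return `M x M` matrix with entry `(i, k) = dp_k / dx_i`.
#' @export
jacobian_p <- function(model, x, h = 1e-6) {
  M <- model$M
  assert_density(x, M)
  ref <- reference_state(M)
  if (x[ref] < 2 * h && x[ref] > 0) {
    stop("boundary-derivative error: reference coordinate too close to the simplex boundary",
         call. = FALSE)
  }
  J <- matrix(0, M, M)
  for (i in seq_len(M)) {
    if (i == ref) next
    d <- numeric(M)
    d[i] <- h
    d[ref] <- -h
    xp <- x + d
    xm <- x - d
    if (any(xp < -1e-15) || any(xm < -1e-15)) {
      stop("boundary-derivative error: finite-difference probe leaves the simplex",
           call. = FALSE)
    }
    pp <- null_eigenvector(model, pmax(xp, 0))
    pm <- null_eigenvector(model, pmax(xm, 0))
    J[i, ] <- (pp - pm) / (2 * h)
  }
  attr(J, "ref") <- ref
  J
}

# Eigenvalues of the reduced (tangent-space) Jacobian of p.
jacobian_p_eigenvalues <- function(model, x, h = 1e-6) {
  J <- jacobian_p(model, x, h = h)
  ref <- attr(J, "ref")
  eigen(J[-ref, -ref, drop = FALSE], only.values = TRUE)$values
}

#' Self-consistent critical points of the density dynamics
#'
#' Finds the fixed points of the map `x -> p(x)` (equivalently the zeros of
#' the deterministic flow) by multi-start damped Newton iteration in reduced
#' simplex coordinates. Each point is classified stable/unstable from the
#' eigenvalues of the reduced Jacobian of `p`: stable iff every eigenvalue
#' has real part `< 1` (strictly; values within `1e-9` of 1 are flagged
#' marginal).
#'
#' @param model A [state_graph_model()].
#' @param n_starts Number of seeded random starts added to the deterministic
#'   grid of starting points.
#' @param seed Integer seed for the random starts.
#' @param tol Convergence tolerance on the l1 residual `|p(x) - x|`.
#' @return List of `"critical_point"` objects with fields `x_star`,
#'   `jacobian_eigenvalues`, `stable`, `marginal`, `residual`.
#' @export
find_critical_points <- function(model, n_starts = 20L, seed = 1L,
                                 tol = 1e-12) {
  stopifnot(n_starts >= 1)
  M <- model$M
  ref <- reference_state(M)
  free <- setdiff(seq_len(M), ref)

  embed <- function(y) {
    x <- numeric(M)
    x[free] <- y
    x[ref] <- 1 - sum(y)
    x
  }
  gfun <- function(y) {
    x <- embed(y)
    (null_eigenvector(model, x) - x)[free]
  }

  starts <- simplex_grid_starts(M - 1, by = 0.2)
  set.seed(seed)
  for (k in seq_len(n_starts)) {
    r <- stats::rexp(M)
    starts[[length(starts) + 1]] <- (r / sum(r))[free]
  }

  found <- list()
  for (y0 in starts) {
    y <- newton_on_simplex(gfun, y0, tol = tol)
    if (is.null(y)) next
    x <- embed(y)
    resid <- sum(abs(null_eigenvector(model, x) - x))
    if (resid > 1e-9) next
    dup <- any(vapply(found, function(cp) max(abs(cp$x_star - x)) < 1e-6,
                      logical(1)))
    if (dup) next
    ev <- jacobian_p_eigenvalues(model, x)
    found[[length(found) + 1]] <- structure(
      list(x_star = x,
           jacobian_eigenvalues = ev,
           stable = all(Re(ev) < 1 - 1e-9),
           marginal = any(abs(Re(ev) - 1) <= 1e-9),
           residual = resid),
      class = "critical_point")
  }
  if (!length(found)) {
    stop("no critical point found from any start", call. = FALSE)
  }
  # deterministic ordering: by first coordinate
  found[order(vapply(found, function(cp) cp$x_star[1], numeric(1)))]
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("<critical_point> x* = (%s)  %s%s  max Re(eig) = %.6g\n",
              paste(sprintf("%.6f", x$x_star), collapse = ", "),
              if (x$stable) "stable" else "unstable",
              if (x$marginal) " (marginal)" else "",
              max(Re(x$jacobian_eigenvalues))))
  invisible(x)
}

# Deterministic grid of starting points in the open reduced simplex.
simplex_grid_starts <- function(d, by = 0.2) {
  vals <- seq(by / 2, 1 - by / 2, by = by)
  grid <- expand.grid(rep(list(vals), d))
  keep <- rowSums(grid) < 1 - 1e-9
  lapply(which(keep), function(i) as.numeric(grid[i, ]))
}

# Damped Newton with finite-difference Jacobian, constrained to the reduced
# simplex (all coordinates >= 0, sum <= 1). Returns NULL on failure.
newton_on_simplex <- function(g, y0, tol = 1e-12, max_iter = 60L, h = 1e-7) {
  y <- y0
  d <- length(y)
  clamp <- function(y) {
    y <- pmax(y, 0)
    s <- sum(y)
    if (s > 1) y <- y / (s + 1e-12)
    y
  }
  for (it in seq_len(max_iter)) {
    gy <- tryCatch(g(y), error = function(e) NULL)
    if (is.null(gy) || any(!is.finite(gy))) return(NULL)
    if (sum(abs(gy)) < tol) return(y)
    J <- matrix(0, d, d)
    for (j in seq_len(d)) {
      e <- numeric(d)
      e[j] <- h
      gp <- tryCatch(g(clamp(y + e)), error = function(e) NULL)
      gm <- tryCatch(g(clamp(y - e)), error = function(e) NULL)
      if (is.null(gp) || is.null(gm)) return(NULL)
      J[, j] <- (gp - gm) / (2 * h)
    }
    step <- tryCatch(solve(J, gy), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damping: backtrack until the residual decreases
    lam <- 1
    repeat {
      ynew <- clamp(y - lam * step)
      gn <- tryCatch(g(ynew), error = function(e) NULL)
      if (!is.null(gn) && all(is.finite(gn)) &&
          (sum(abs(gn)) < sum(abs(gy)) || lam < 1e-3)) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    if (max(abs(ynew - y)) < 1e-15) return(if (sum(abs(gy)) < 1e-9) y else NULL)
    y <- ynew
  }
  if (sum(abs(g(y))) < 1e-9) y else NULL
}

#' Scan a model family for a bifurcation of the tracked critical point
#'
#' For each parameter value the critical point is followed by numerical
#' continuation (Newton restarted from the previous solution) and the
#' spectral indicator -- the largest real part of the eigenvalues of the
#' reduced Jacobian of `p` -- is recorded. A bifurcation of the tracked
#' branch is signalled by the indicator crossing 1; the crossing is refined
#' by bisection to `tol`.
#'
#' @param model_family Function mapping a scalar parameter to a
#'   [state_graph_model()].
#' @param param_grid Sorted numeric vector of parameter values.
#' @param tol Bisection tolerance on the crossing parameter.
#' @return A `data.frame` with columns `param` and `indicator`, with
#'   attribute `"crossing"` (the refined bifurcation parameter, or `NA` with
#'   a warning when the indicator never crosses 1 on the grid).
#' @export
bifurcation_scan <- function(model_family, param_grid, tol = 1e-6) {
  stopifnot(!is.unsorted(param_grid), length(param_grid) >= 2)

  track <- local({
    x_prev <- NULL
    function(param) {
      model <- model_family(param)
      M <- model$M
      ref <- reference_state(M)
      free <- setdiff(seq_len(M), ref)
      gfun <- function(y) {
        x <- numeric(M)
        x[free] <- y
        x[ref] <- 1 - sum(y)
        (null_eigenvector(model, x) - x)[free]
      }
      y0 <- if (is.null(x_prev)) {
        cps <- find_critical_points(model, n_starts = 5L, seed = 1L)
        stab <- Filter(function(cp) cp$stable, cps)
        (if (length(stab)) stab[[1]] else cps[[1]])$x_star[free]
      } else x_prev[free]
      y <- newton_on_simplex(gfun, y0)
      if (is.null(y)) stop("continuation lost the critical point", call. = FALSE)
      x <- numeric(M)
      x[free] <- y
      x[ref] <- 1 - sum(y)
      x_prev <<- x
      max(Re(jacobian_p_eigenvalues(model, x)))
    }
  })

  indicator <- vapply(param_grid, track, numeric(1))
  res <- data.frame(param = param_grid, indicator = indicator)

  cross <- which(diff(sign(indicator - 1)) != 0)
  if (!length(cross)) {
    warning("spectral indicator never crosses 1 on the grid; no bifurcation located")
    attr(res, "crossing") <- NA_real_
    return(res)
  }
  lo <- param_grid[cross[1]]
  hi <- param_grid[cross[1] + 1]
  flo <- indicator[cross[1]] - 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fmid <- track(mid) - 1
    if (sign(fmid) == sign(flo)) {
      lo <- mid
      flo <- fmid
    } else {
      hi <- mid
    }
  }
  attr(res, "crossing") <- (lo + hi) / 2
  res
}
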