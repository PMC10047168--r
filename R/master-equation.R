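#' Sparse generator of the one-step master equation
#'
#' Assembles the transition-rate matrix `W` of the master equation on the
#' conserved-`N` lattice: for every ordered species pair `(i, j)` and every
#' state with `n_j >= 1` there is a one-step move `n -> n - e_j + e_i` with
#' rate `pi_ij(n / N) * n_j` (time rescaled by `N`, so the stationary
#' distribution is unchanged and relaxation rates are O(1)). Diagonal entries
#' balance the columns, so every column of `W` sums to zero.
#'
#' @param model A [state_graph_model()].
#' @param N Particle number.
#' @return Object of class `"me_generator"` with fields `lattice`, `W`
#'   (a `dgCMatrix`), and `model`.
#' @export
build_generator <- function(model, N) {
  lat <- simplex_lattice(N, model$M)
  M <- model$M
  S <- lat$size
  states <- lat$states

  # per-state rate matrices, flattened to S x (M*M); column (i-1)*M + j
  # holds pi_ji? -- store column-major: entry [s, (j-1)*M + i] = pi_ij(x_s)
  rates_flat <- t(apply(states, 1, function(n) rate_matrix(model, n / N)))

  ii <- vector("list", M * (M - 1))
  jj <- ii
  xx <- ii
  k <- 0
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      col <- (j - 1L) * M + i  # pi_ij stored column-major
      rate_ij <- rates_flat[, col]
      src <- which(states[, j] >= 1L & rate_ij > 0)
      if (!length(src)) next
      tgt_states <- states[src, , drop = FALSE]
      tgt_states[, j] <- tgt_states[, j] - 1L
      tgt_states[, i] <- tgt_states[, i] + 1L
      k <- k + 1
      ii[[k]] <- lattice_index(lat, tgt_states)
      jj[[k]] <- src
      xx[[k]] <- rate_ij[src] * states[src, j]
    }
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(S, S))
  Matrix::diag(W) <- 0
  W <- W - Matrix::Diagonal(S, Matrix::colSums(W))
  structure(list(lattice = lat, W = W, model = model), class = "me_generator")
}

#' @export
print.me_generator <- function(x, ...) {
  cat(sprintf("<me_generator> '%s' on N = %d (%d states), %d nonzeros\n",
              x$model$name, x$lattice$N, x$lattice$size,
              length(x$W@x)))
  invisible(x)
}

#' Stationary distribution by direct null-space solve
#'
#' The probability-normalized right null vector of `W`. Because the left
#' null vector of a conservative generator is the all-ones row, replacing a
#' single row of `W` by ones yields a nonsingular sparse system whose
#' solution is the stationary distribution normalized to sum 1; the solve
#' uses the sparse LU factorization of the Matrix package. The residual
#' `|W rho|_1` is verified to be below `1e-10` (with a dense-eigen fallback
#' for small lattices if the direct solve degrades).
#'
#' @param gen An [build_generator()] result.
#' @return A [lattice_distribution()].
#' @export
stationary_nullspace <- function(gen) {
  stopifnot(inherits(gen, "me_generator"))
  W <- gen$W
  S <- nrow(W)
  A <- W
  A[1, ] <- 1
  b <- c(1, numeric(S - 1))
  rho <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) NULL)
  ok <- !is.null(rho) && all(is.finite(rho)) &&
    sum(abs(W %*% pmax(rho, 0) / sum(pmax(rho, 0)))) < 1e-10
  if (!ok) {
    if (S > 5000) {
      stop("reducible-chain error: sparse null-space solve failed and the lattice is too large for the dense fallback",
           call. = FALSE)
    }
    e <- eigen(as.matrix(W))
    lam <- abs(e$values)
    if (sum(lam < 1e-8 * max(lam, 1)) > 1) {
      stop("reducible-chain error: generator null space has dimension > 1",
           call. = FALSE)
    }
    rho <- Re(e$vectors[, which.min(lam)])
    if (sum(rho) < 0) rho <- -rho
  }
  rho <- pmax(rho, 0)
  dist <- lattice_distribution(gen$lattice, rho)
  resid <- sum(abs(W %*% dist$prob))
  if (resid > 1e-10) {
    stop("stationary residual ", format(resid), " exceeds 1e-10", call. = FALSE)
  }
  dist
}

#' Integrate the master equation to stationarity with adaptive RK5(4)
#'
#' Dormand-Prince embedded Runge-Kutta integration of `drho/dt = W rho`,
#' with step-size control on the embedded 4th-order error estimate. The
#' integration stops when the stationarity residual `|W rho|_1` falls below
#' `stop_residual`, or at `t_max`. Probability mass is conserved by the
#' generator up to roundoff; the drift of `sum(rho)` is monitored and
#' renormalized (it must stay below `1e-9`).
#'
#' @param gen An [build_generator()] result.
#' @param rho0 Initial [lattice_distribution()]; default uniform over the
#'   lattice (symmetric, avoids biasing toward one basin).
#' @param rtol,atol Local error tolerances of the embedded step control.
#' @param stop_residual Stationarity threshold on `|W rho|_1`.
#' @param t_max Time horizon; with the default `Inf` the integration errors
#'   out if `max_steps` is exhausted before stationarity, while a finite
#'   `t_max` returns the non-converged state with a warning.
#' @param snapshot_dt Spacing of trajectory snapshots used for the distance
#'   trace.
#' @param reference Optional [lattice_distribution()] against which the
#'   trace distances are measured; default is the trajectory's final state.
#' @param max_steps Hard cap on accepted steps.
#' @return List with fields `dist` (final [lattice_distribution()]), `trace`
#'   (`data.frame` of `time` and l1 `distance` to the reference),
#'   `converged`, and `residual`.
#' @export
integrate_to_stationarity <- function(gen, rho0 = NULL, rtol = 1e-12,
                                      atol = 1e-16, stop_residual = 1e-10,
                                      t_max = Inf, snapshot_dt = 0.5,
                                      reference = NULL, max_steps = 5e5L) {
  stopifnot(inherits(gen, "me_generator"))
  W <- gen$W
  S <- nrow(W)
  y <- if (is.null(rho0)) rep(1 / S, S) else {
    stopifnot(inherits(rho0, "lattice_distribution"),
              rho0$lattice$size == S)
    rho0$prob
  }
  mv <- function(v) as.vector(W %*% v)

  snaps <- list()
  times <- numeric(0)
  take_snapshot <- function(t, y) {
    snaps[[length(snaps) + 1]] <<- y
    times[length(times) + 1] <<- t
  }

  t <- 0
  h <- 1e-4
  nst <- 0L
  next_snap <- 0
  k1 <- mv(y)
  converged <- sum(abs(k1)) < stop_residual
  # the achievable residual scales with the local error tolerance; detect a
  # stalled floor instead of burning the step budget against it
  best_resid <- sum(abs(k1))
  best_step <- 0L
  stalled <- FALSE
  while (!converged) {
    if (t >= next_snap - 1e-12) {
      take_snapshot(t, y)
      next_snap <- next_snap + snapshot_dt
    }
    if (t >= t_max) break
    if (nst >= max_steps) {
      if (is.finite(t_max)) break
      stop("convergence error: residual ", format(sum(abs(k1))),
           " after ", nst, " steps", call. = FALSE)
    }
    k2 <- mv(y + h * (1 / 5) * k1)
    k3 <- mv(y + h * (3 / 40 * k1 + 9 / 40 * k2))
    k4 <- mv(y + h * (44 / 45 * k1 - 56 / 15 * k2 + 32 / 9 * k3))
    k5 <- mv(y + h * (19372 / 6561 * k1 - 25360 / 2187 * k2 +
                        64448 / 6561 * k3 - 212 / 729 * k4))
    k6 <- mv(y + h * (9017 / 3168 * k1 - 355 / 33 * k2 + 46732 / 5247 * k3 +
                        49 / 176 * k4 - 5103 / 18656 * k5))
    y5 <- y + h * (35 / 384 * k1 + 500 / 1113 * k3 + 125 / 192 * k4 -
                     2187 / 6784 * k5 + 11 / 84 * k6)
    k7 <- mv(y5)
    errv <- h * ((35 / 384 - 5179 / 57600) * k1 +
                   (500 / 1113 - 7571 / 16695) * k3 +
                   (125 / 192 - 393 / 640) * k4 +
                   (-2187 / 6784 + 92097 / 339200) * k5 +
                   (11 / 84 - 187 / 2100) * k6 - (1 / 40) * k7)
    err <- max(abs(errv))
    tol <- atol + rtol * max(abs(y))
    if (err <= tol) {
      t <- t + h
      y <- y5
      k1 <- k7  # FSAL
      nst <- nst + 1L
      resid <- sum(abs(k1))
      if (resid < stop_residual) converged <- TRUE
      if (resid < 0.99 * best_resid) {
        best_resid <- resid
        best_step <- nst
      } else if (nst - best_step > 5000L) {
        stalled <- TRUE
        break
      }
    } else {
      k1 <- mv(y)
    }
    h <- h * min(5, max(0.2, 0.9 * (tol / max(err, 1e-300))^0.2))
    if (is.finite(t_max)) h <- min(h, max(t_max - t, 1e-12))
  }
  drift <- abs(sum(y) - 1)
  if (drift > 1e-9) {
    warning("probability drift ", format(drift), " exceeded 1e-9")
  }
  y <- pmax(y, 0)
  y <- y / sum(y)
  take_snapshot(t, y)

  if (!converged) {
    if (stalled && !is.finite(t_max)) {
      stop("convergence error: residual stalled at ", format(best_resid),
           " (the floor set by rtol/atol); tighten the tolerances or raise stop_residual",
           call. = FALSE)
    }
    if (is.finite(t_max)) {
      warning("integration stopped at t = ", format(t), " with residual ",
              format(sum(abs(mv(y)))))
    }
  }

  ref <- if (is.null(reference)) y else {
    stopifnot(inherits(reference, "lattice_distribution"))
    reference$prob
  }
  dist <- vapply(snaps, function(s) sum(abs(s - ref)), numeric(1))
  list(dist = lattice_distribution(gen$lattice, y),
       trace = data.frame(time = times, distance = dist),
       converged = converged,
       residual = sum(abs(mv(y))))
}

#' Stochastic sampling of the stationary distribution (Gillespie)
#'
#' Continuous-time simulation of the one-step process: propensity
#' `pi_ij(n / N) * n_j` for every ordered pair `(i, j)`, exponential waiting
#' times, and instantaneous propensity update after every event. Occupancy is
#' time-weighted (each visited state contributes its sojourn time) after a
#' burn-in number of events. Reproducible given `seed`.
#'
#' @param model A [state_graph_model()].
#' @param N Particle number.
#' @param n_events Total number of jump events to simulate.
#' @param burn_in Events discarded before occupancy accumulation starts.
#' @param seed Integer seed.
#' @param n0 Optional initial occupation vector (defaults to the most even
#'   split of `N` over the `M` states).
#' @return A [lattice_distribution()] of time-weighted empirical occupancy.
#' @export
gillespie_sample <- function(model, N, n_events, burn_in = 0L, seed = 1L,
                             n0 = NULL) {
  stopifnot(n_events > burn_in, burn_in >= 0)
  M <- model$M
  lat <- simplex_lattice(N, M)
  if (is.null(n0)) {
    n0 <- rep(N %/% M, M)
    rem <- N - sum(n0)
    if (rem > 0) n0[seq_len(rem)] <- n0[seq_len(rem)] + 1L
  }
  stopifnot(length(n0) == M, sum(n0) == N, all(n0 >= 0))

  pairs <- which(diag(M) == 0, arr.ind = TRUE)  # all ordered (i, j), i != j
  pi_i <- pairs[, 1]
  pi_j <- pairs[, 2]
  npair <- nrow(pairs)

  set.seed(seed)
  n <- as.numeric(n0)
  occ <- numeric(lat$size)
  for (ev in seq_len(n_events)) {
    m <- rate_matrix(model, n / N)
    prop <- m[cbind(pi_i, pi_j)] * n[pi_j]
    tot <- sum(prop)
    if (tot <= 0) {
      warning("absorbing state reached after ", ev - 1L,
              " events; returning occupancy so far")
      break
    }
    tau <- stats::rexp(1, tot)
    if (ev > burn_in) {
      idx <- lattice_index(lat, n)
      occ[idx] <- occ[idx] + tau
    }
    mvix <- sample.int(npair, 1L, prob = prop)
    n[pi_j[mvix]] <- n[pi_j[mvix]] - 1
    n[pi_i[mvix]] <- n[pi_i[mvix]] + 1
  }
  lattice_distribution(lat, occ)
}

#' Relaxation rate from a distance trace
#'
#' Fits the slope of `log(distance)` against time on the final decade of
#' decay, ignoring points below a noise floor (the l1 floor left by the
#' integrator's finite tolerance). For a linear model the fitted rate equals
#' the magnitude of the generator's second-smallest eigenvalue (the Fiedler
#' eigenvalue of the lifted dynamics).
#'
#' @param trace A `data.frame` with columns `time` and `distance`, as
#'   returned by [integrate_to_stationarity()].
#' @param floor Distances below this value are treated as converged noise
#'   and excluded from the fit.
#' @return The fitted exponential decay rate (positive for decaying traces).
#' @export
relaxation_rate <- function(trace, floor = 1e-7) {
  stopifnot(is.data.frame(trace), all(c("time", "distance") %in% names(trace)))
  d <- trace$distance
  t <- trace$time
  ok <- which(d > floor)
  if (length(ok) < 4) {
    stop("insufficient-data error: fewer than 4 trace points above the floor",
         call. = FALSE)
  }
  dend <- d[max(ok)]
  sel <- ok[d[ok] <= 10 * dend]
  if (length(sel) < 4) sel <- utils::tail(ok, 4)
  fit <- stats::lm(log(d[sel]) ~ t[sel])
  -unname(stats::coef(fit)[2])
}
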