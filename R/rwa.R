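#' Random Walk Approximation of the stationary distribution
#'
#' The package's core method. For every lattice state `n` the multinomial-like
#' weight
#' \deqn{\rho(n) = C(N)\, N! \prod_k p_k(n/N)^{n_k} / n_k!}
#' is evaluated with the Laplacian null eigenvector `p` taken at that state's
#' own density `x = n / N` -- the rates are *not* frozen at a reference
#' point, which is what makes the approximation global and able to contain a
#' bifurcation. All products are computed in log space through `lgamma`
#' (N! overflows double precision near N = 171), with the conventions
#' `0 * log 0 = 0` and `p_k = 0, n_k > 0 =>` weight 0. The normalization
#' `C(N)` is obtained by exact summation over the lattice.
#'
#' For a linear model (constant rates) the RWA coincides state-by-state with
#' the exact multinomial stationary solution.
#'
#' @param model A [state_graph_model()].
#' @param N Particle number.
#' @return Object of class `"rwa_result"` with fields `dist` (a
#'   [lattice_distribution()]), `log_norm` (`log C(N)`, the log of the factor
#'   that normalizes the raw multinomial-like weights), and `jacobian_norm`
#'   (spectral norm of the Jacobian of `p` at the stable critical point; the
#'   predicted scale of the l1 error).
#' @export
rwa_distribution <- function(model, N) {
  lat <- simplex_lattice(N, model$M)
  lgN <- lgamma(N + 1)
  logw <- apply(lat$states, 1, function(n) {
    p <- null_vector_of_rates(rate_matrix(model, n / N))
    act <- n > 0
    if (any(p[act] == 0)) return(-Inf)
    lgN + sum(n[act] * log(p[act]) - lgamma(n[act] + 1))
  })
  lse <- log_sum_exp(logw)
  dist <- lattice_distribution(lat, exp(logw - lse))
  jn <- tryCatch(jacobian_norm_bound(model), error = function(e) NA_real_)
  structure(list(dist = dist,
                 log_norm = -lse,   # rho = exp(log_norm) * raw weight
                 jacobian_norm = jn),
            class = "rwa_result")
}

#' @export
print.rwa_result <- function(x, ...) {
  cat(sprintf("<rwa_result> log C(N) = %.6g, |dp/dx| at x* = %.4g\n",
              x$log_norm, x$jacobian_norm))
  print(x$dist)
  invisible(x)
}

log_sum_exp <- function(lw) {
  m <- max(lw[is.finite(lw)])
  m + log(sum(exp(lw - m)))
}

#' Master-equation residual of a trial stationary distribution
#'
#' Applies the full one-step generator to `dist` and returns the l1 norm of
#' the result, `|W rho|_1`. The residual is zero exactly when `dist` is
#' stationary; for the RWA it is the quantity whose magnitude is predicted
#' by the Jacobian norm of `p` and which is independent of `N` away from a
#' bifurcation.
#'
#' @param model A [state_graph_model()].
#' @param dist A [lattice_distribution()].
#' @param gen Optional pre-built [build_generator()] result (must share the
#'   lattice of `dist`); built on the fly when omitted.
#' @return Nonnegative scalar.
#' @export
me_residual_l1 <- function(model, dist, gen = NULL) {
  stopifnot(inherits(dist, "lattice_distribution"))
  if (is.null(gen)) gen <- build_generator(model, dist$lattice$N)
  if (gen$lattice$size != dist$lattice$size ||
      gen$lattice$N != dist$lattice$N) {
    stop("dimension error: generator and distribution lattices differ",
         call. = FALSE)
  }
  sum(abs(gen$W %*% dist$prob))
}

#' Predicted scale of the RWA error
#'
#' Spectral norm (largest singular value) of the Jacobian of the null
#' eigenvector `p` at the stable critical point. By the error analysis of
#' the method, the l1 distance between the RWA and the exact stationary
#' solution is of this order, independent of `N`. When several stable
#' critical points exist the largest norm is reported.
#'
#' @param model A [state_graph_model()].
#' @return Nonnegative scalar.
#' @export
jacobian_norm_bound <- function(model) {
  cps <- find_critical_points(model)
  stable <- Filter(function(cp) cp$stable, cps)
  if (!length(stable)) {
    stop("no stable critical point exists for this model", call. = FALSE)
  }
  max(vapply(stable, function(cp) {
    J <- jacobian_p(model, cp$x_star)
    ref <- attr(J, "ref")
    max(svd(J[-ref, -ref, drop = FALSE])$d)
  }, numeric(1)))
}

#' Locate and classify the modes of an RWA distribution
#'
#' Local maxima of the RWA over the lattice under the one-step
#' nearest-neighbor moves `n -> n + e_i - e_j` (the adjacency of the process
#' itself). Each mode is labeled `"consistent"` when its density lies within
#' `2 / N` (infinity norm) of a self-consistent critical point of the
#' deterministic dynamics, and `"spurious"` otherwise -- after a bifurcation
#' the RWA may acquire stationary points that the average dynamics does not
#' have, and this diagnostic reports them.
#'
#' @param model A [state_graph_model()].
#' @param result An [rwa_distribution()] result (or any
#'   [lattice_distribution()]).
#' @return A `data.frame` with one row per mode: the occupation vector
#'   columns `n_1 ... n_M`, `prob`, and `label`; attribute `"spurious"` is
#'   `TRUE` if any mode is spurious.
#' @export
mode_check <- function(model, result) {
  dist <- if (inherits(result, "rwa_result")) result$dist else result
  stopifnot(inherits(dist, "lattice_distribution"))
  lat <- dist$lattice
  modes_idx <- lattice_local_maxima(dist)
  cps <- find_critical_points(model)
  dens <- lat$states[modes_idx, , drop = FALSE] / lat$N
  label <- vapply(seq_along(modes_idx), function(r) {
    near <- any(vapply(cps, function(cp)
      max(abs(dens[r, ] - cp$x_star)) <= 2 / lat$N, logical(1)))
    if (near) "consistent" else "spurious"
  }, character(1))
  out <- data.frame(lat$states[modes_idx, , drop = FALSE])
  names(out) <- paste0("n_", seq_len(lat$M))
  out$prob <- dist$prob[modes_idx]
  out$label <- label
  attr(out, "spurious") <- any(label == "spurious")
  out[order(-out$prob), , drop = FALSE]
}

# Indices of strict local maxima under n -> n + e_i - e_j moves.
lattice_local_maxima <- function(dist) {
  lat <- dist$lattice
  p <- dist$prob
  is_max <- rep(TRUE, lat$size)
  M <- lat$M
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      nb <- lat$states
      nb[, j] <- nb[, j] - 1L
      nb[, i] <- nb[, i] + 1L
      idx <- lattice_index(lat, nb)
      has <- !is.na(idx)
      is_max[has] <- is_max[has] & (p[has] >= p[idx[has]])
    }
  }
  which(is_max & p > 0)
}
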