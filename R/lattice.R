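#' Enumerate the conserved-N simplex lattice
#'
#' All occupation vectors `n = (n_1, ..., n_M)` of nonnegative integers with
#' `sum(n) = N`, ordered lexicographically on the first `M - 1` coordinates
#' (the last is implied by the conservation law). The enumeration has
#' `choose(N + M - 1, M - 1)` states; for `M = 3` that is
#' `(N + 1)(N + 2) / 2`.
#'
#' @param N Particle number (`>= 1`).
#' @param M Number of states (`>= 2`).
#' @return Object of class `"simplex_lattice"` with fields `N`, `M`,
#'   `states` (a `size x M` integer matrix) and `size`.
#' @export
simplex_lattice <- function(N, M) {
  stopifnot(N >= 1, M >= 2, N == round(N), M == round(M))
  size <- choose(N + M - 1, M - 1)
  if (size > 5e7) {
    stop("lattice too large: ", format(size), " states exceeds the 5e7 guard",
         call. = FALSE)
  }
  states <- enumerate_states(as.integer(N), as.integer(M))
  structure(list(N = as.integer(N), M = as.integer(M),
                 states = states, size = nrow(states)),
            class = "simplex_lattice")
}

# Recursive lexicographic enumeration of nonnegative integer M-tuples
# summing to N.
enumerate_states <- function(N, M) {
  if (M == 1) return(matrix(N, 1, 1))
  if (M == 2) return(cbind(0:N, N:0))
  blocks <- lapply(0:N, function(a) {
    sub <- enumerate_states(N - a, M - 1L)
    cbind(rep.int(a, nrow(sub)), sub)
  })
  do.call(rbind, blocks)
}

#' @export
print.simplex_lattice <- function(x, ...) {
  cat(sprintf("<simplex_lattice> N = %d particles, M = %d states, %d lattice states\n",
              x$N, x$M, x$size))
  invisible(x)
}

#' Position of occupation vectors in the lattice enumeration
#'
#' Inverse of the enumeration: `lattice_index(lat, lat$states) == 1:size`.
#' Rows that are not valid lattice states (negative entries or wrong total)
#' get `NA`. For `M = 3` a closed-form index is used; the general case falls
#' back to key matching.
#'
#' @param lattice A [simplex_lattice()].
#' @param states Integer matrix with `M` columns (or a single length-`M`
#'   vector).
#' @return Integer vector of positions.
#' @export
lattice_index <- function(lattice, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  stopifnot(ncol(states) == lattice$M)
  N <- lattice$N
  valid <- rowSums(states) == N & rowSums(states >= 0) == lattice$M
  idx <- rep(NA_integer_, nrow(states))
  if (lattice$M == 3) {
    a <- states[valid, 1]
    b <- states[valid, 2]
    idx[valid] <- as.integer(a * (N + 1) - a * (a - 1) / 2 + b + 1)
  } else {
    keys <- apply(lattice$states, 1, paste, collapse = ",")
    qk <- apply(states[valid, , drop = FALSE], 1, paste, collapse = ",")
    idx[valid] <- match(qk, keys)
  }
  idx
}

#' Probability distribution over a simplex lattice
#'
#' The common container returned by every stationary-solution method in the
#' package (exact, RWA, SSE, multinomial, Gillespie).
#'
#' @param lattice A [simplex_lattice()].
#' @param prob Nonnegative weight per lattice state.
#' @param normalize Rescale `prob` to sum to 1 (default). With
#'   `normalize = FALSE` the vector must already be normalized to `1e-9`.
#' @return Object of class `"lattice_distribution"`.
#' @export
lattice_distribution <- function(lattice, prob, normalize = TRUE) {
  stopifnot(inherits(lattice, "simplex_lattice"), length(prob) == lattice$size)
  if (any(prob < 0)) {
    if (min(prob) < -1e-12 * max(prob)) {
      stop("negative probabilities in lattice distribution", call. = FALSE)
    }
    prob <- pmax(prob, 0)
  }
  s <- sum(prob)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero distribution", call. = FALSE)
    prob <- prob / s
  } else if (abs(s - 1) > 1e-9) {
    stop("distribution not normalized: sum = ", format(s), call. = FALSE)
  }
  structure(list(lattice = lattice, prob = as.numeric(prob)),
            class = "lattice_distribution")
}

#' @export
print.lattice_distribution <- function(x, ...) {
  imax <- which.max(x$prob)
  cat(sprintf("<lattice_distribution> on N = %d, M = %d (%d states); max p = %.4g at n = (%s)\n",
              x$lattice$N, x$lattice$M, x$lattice$size, x$prob[imax],
              paste(x$lattice$states[imax, ], collapse = ", ")))
  invisible(x)
}

#' First and second moments of a lattice distribution
#'
#' Exact mean vector and covariance matrix of the occupation numbers `n`
#' by direct summation. For the multinomial stationary solution of a linear
#' model the covariance has the closed form `C = N diag(p) - N p p'`, which
#' serves as the reference oracle in the test suite.
#'
#' @param dist A [lattice_distribution()].
#' @return List with fields `mean` (length `M`) and `cov` (`M x M`).
#' @export
moments <- function(dist) {
  stopifnot(inherits(dist, "lattice_distribution"))
  S <- dist$lattice$states
  w <- dist$prob
  mu <- as.numeric(crossprod(S, w))
  second <- crossprod(S, S * w)
  list(mean = mu, cov = as.matrix(second - tcrossprod(mu)))
}
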