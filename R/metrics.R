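#' l1 distance between two lattice distributions
#'
#' `sum |p - q|` over all lattice states; ranges from 0 (equality) to 2
#' (disjoint supports). This is the metric in which the RWA error analysis
#' is formulated: away from a bifurcation the l1 distance between the RWA
#' and the exact stationary solution is independent of `N`.
#'
#' @param p,q [lattice_distribution()]s on the same lattice.
#' @return Scalar in `[0, 2]`.
#' @export
l1_distance <- function(p, q) {
  check_same_lattice(p, q)
  sum(abs(p$prob - q$prob))
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JS(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and
#' base-2 logarithms: symmetric, and normalized so that disjoint
#' distributions score exactly 1. Terms with zero probability contribute 0.
#' The square root of this quantity (the Jensen-Shannon *distance*, see
#' [js_distance()]) is the scale on which percentage errors between
#' stationary approximations are conventionally reported.
#'
#' @inheritParams l1_distance
#' @return Scalar in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  check_same_lattice(p, q)
  a <- p$prob
  b <- q$prob
  m <- (a + b) / 2
  kl <- function(u, v) {
    i <- u > 0
    sum(u[i] * log2(u[i] / v[i]))
  }
  min(max((kl(a, m) + kl(b, m)) / 2, 0), 1)
}

#' Jensen-Shannon distance (base 2)
#'
#' Square root of [js_divergence()]; a true metric, also bounded by 1.
#'
#' @inheritParams l1_distance
#' @return Scalar in `[0, 1]`.
#' @export
js_distance <- function(p, q) sqrt(js_divergence(p, q))

#' Scale-free covariance error between two lattice distributions
#'
#' Frobenius norm of the difference of the occupation-number covariance
#' matrices, divided by `N` so that values are comparable across system
#' sizes (the covariance itself scales linearly with `N`).
#'
#' @inheritParams l1_distance
#' @return Nonnegative scalar.
#' @export
covariance_error <- function(p, q) {
  check_same_lattice(p, q)
  norm(moments(p)$cov - moments(q)$cov, "F") / p$lattice$N
}

check_same_lattice <- function(p, q) {
  stopifnot(inherits(p, "lattice_distribution"),
            inherits(q, "lattice_distribution"))
  if (p$lattice$N != q$lattice$N || p$lattice$M != q$lattice$M) {
    stop("dimension error: distributions live on different lattices",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Compare approximation methods against a reference solution
#'
#' Computes the requested stationary approximations and the reference on
#' the same lattice and reports one row per method with the l1 distance,
#' Jensen-Shannon divergence, scale-free covariance error, and whether the
#' mode sets agree (every mode of the method within `2/N` in density of a
#' mode of the reference).
#'
#' @param model A [state_graph_model()].
#' @param N Particle number.
#' @param methods Character vector from
#'   `c("rwa", "sse", "multinomial", "exact", "gillespie")`.
#' @param reference Reference method (default `"exact"`, the null-space
#'   solve).
#' @param seed Seed forwarded to stochastic methods.
#' @param gillespie_events Event budget when `"gillespie"` is requested.
#' @return A `data.frame` with columns `method`, `reference`, `l1`, `js`,
#'   `cov_error`, `modes_match`.
#' @export
compare_methods <- function(model, N, methods = c("rwa", "sse", "multinomial"),
                            reference = "exact", seed = 1L,
                            gillespie_events = 1e6) {
  all_methods <- c("rwa", "sse", "multinomial", "exact", "gillespie")
  stopifnot(length(methods) >= 1, all(methods %in% all_methods),
            reference %in% all_methods)
  ref_dist <- compute_method(model, N, reference, seed = seed,
                             gillespie_events = gillespie_events)
  ref_modes <- lattice_local_maxima(ref_dist)
  rows <- lapply(methods, function(meth) {
    d <- compute_method(model, N, meth, seed = seed,
                        gillespie_events = gillespie_events)
    mm <- modes_agree(d, ref_dist, ref_modes)
    data.frame(method = meth, reference = reference,
               l1 = l1_distance(d, ref_dist),
               js = js_divergence(d, ref_dist),
               cov_error = covariance_error(d, ref_dist),
               modes_match = mm)
  })
  do.call(rbind, rows)
}

# Dispatch a method name to its solver; shared by compare_methods, sweeps
# and the command-line tool.
compute_method <- function(model, N, method, seed = 1L,
                           gillespie_events = 1e6) {
  switch(method,
    rwa = rwa_distribution(model, N)$dist,
    sse = sse_distribution(model, N),
    multinomial = multinomial_approximation(model, N),
    exact = stationary_nullspace(build_generator(model, N)),
    gillespie = gillespie_sample(model, N, n_events = gillespie_events,
                                 burn_in = round(gillespie_events * 0.05),
                                 seed = seed),
    stop("unknown method '", method, "'", call. = FALSE)
  )
}

modes_agree <- function(d, ref_dist, ref_modes) {
  N <- d$lattice$N
  dm <- lattice_local_maxima(d)
  dens_d <- d$lattice$states[dm, , drop = FALSE] / N
  dens_r <- ref_dist$lattice$states[ref_modes, , drop = FALSE] / N
  all(vapply(seq_len(nrow(dens_d)), function(i) {
    any(apply(abs(dens_r - matrix(dens_d[i, ], nrow(dens_r), ncol(dens_r),
                                  byrow = TRUE)), 1, max) <= 2 / N)
  }, logical(1)))
}
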