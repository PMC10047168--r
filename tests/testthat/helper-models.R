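# Shared fixtures: all built in code, no stored data.

# A linear (constant-rate) model: strongly connected, entries in [0.5, 1.5].
random_linear_model <- function(M, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(M * M, 0.5, 1.5), M, M)
  diag(m) <- 0
  force(m)
  state_graph_model(M, function(x) m, name = sprintf("linear-%d", seed))
}

two_state_model <- function(r12 = 1, r21 = 1) {
  state_graph_model(2, function(x) matrix(c(0, r21, r12, 0), 2, 2),
                    name = "two-state")
}

# Independent multinomial oracle via stats::dmultinom (never the package's
# own log-space evaluation).
multinomial_oracle <- function(lattice, p) {
  apply(lattice$states, 1, function(n) stats::dmultinom(n, prob = p))
}

# Random interior simplex points, reproducible.
random_simplex_points <- function(n, M, seed) {
  set.seed(seed)
  t(replicate(n, {
    r <- stats::rexp(M)
    r / sum(r)
  }))
}
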