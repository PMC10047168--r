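test_that("generator columns sum to zero and couple only one-step neighbors", {
  for (gen in list(build_generator(toy_model(0.5), 8),
                   build_generator(pdpc_model(pdpc_params(v2 = 2.6)), 6),
                   build_generator(random_linear_model(4, seed = 6), 5))) {
    W <- gen$W
    expect_lt(max(abs(Matrix::colSums(W))), 1e-12)
    # every off-diagonal entry connects states differing by e_i - e_j
    Wt <- methods::as(W, "TsparseMatrix")
    keep <- Wt@i != Wt@j & Wt@x != 0
    diffs <- gen$lattice$states[Wt@i[keep] + 1L, , drop = FALSE] -
      gen$lattice$states[Wt@j[keep] + 1L, , drop = FALSE]
    expect_true(all(rowSums(abs(diffs)) == 2))
    expect_true(all(rowSums(diffs) == 0))
  }
})

test_that("two-state linear generator has the binomial null vector", {
  # pi12 = pi21 = 1, N = 2: hand-solved 3-state chain -> Binomial(2, 1/2)
  gen <- build_generator(two_state_model(1, 1), 2)
  st <- stationary_nullspace(gen)
  expect_equal(st$prob, c(1 / 4, 1 / 2, 1 / 4), tolerance = 1e-12)
})

test_that("generator matches a brute-force assembly of the explicit 3-state scheme", {
  # independent term-by-term oracle: the eight gain/loss terms of the
  # two-cycle scheme, written directly in (x_A, x_C) density coordinates and
  # rescaled by N
  alpha <- 0.5
  N <- 3
  model <- toy_model(alpha)
  gen <- build_generator(model, N)
  lat <- gen$lattice
  theta <- function(z) 1 - alpha + alpha * (1 - z)^2
  rates_at <- function(xA, xC) c(AB = 1, BA = theta(xA), CB = 1, BC = theta(xC))

  W_oracle <- matrix(0, lat$size, lat$size)
  for (s in seq_len(lat$size)) {
    n <- lat$states[s, ]
    xA <- n[1] / N
    xC <- n[3] / N
    r <- rates_at(xA, xC)
    xB <- 1 - xA - xC
    # loss terms of state s (columns of W): one per admissible move
    moves <- list(
      list(rate = r["AB"] * xB, d = c(+1, -1, 0)),  # B -> A
      list(rate = r["BA"] * xA, d = c(-1, +1, 0)),  # A -> B
      list(rate = r["CB"] * xB, d = c(0, -1, +1)),  # B -> C
      list(rate = r["BC"] * xC, d = c(0, +1, -1))   # C -> B
    )
    for (mv in moves) {
      if (mv$rate <= 0) next
      tgt <- lattice_index(lat, n + mv$d)
      if (is.na(tgt)) next
      W_oracle[tgt, s] <- W_oracle[tgt, s] + mv$rate * N  # rescaled time
      W_oracle[s, s] <- W_oracle[s, s] - mv$rate * N
    }
  }
  expect_equal(as.matrix(gen$W), W_oracle, tolerance = 1e-13,
               ignore_attr = TRUE)
})

test_that("linear stationary solutions equal the multinomial closed form", {
  for (seed in c(1, 2, 3)) {
    model <- random_linear_model(3, seed = seed)
    N <- 25
    st <- stationary_nullspace(build_generator(model, N))
    p <- null_eigenvector(model, rep(1 / 3, 3))
    oracle <- multinomial_oracle(st$lattice, p)
    expect_lt(max(abs(st$prob - oracle)), 1e-9)
  }
})

test_that("reducible lattice chains are detected", {
  # a frozen species (no transitions touching state 3) disconnects the lattice
  frozen <- state_graph_model(3, function(x) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- 1
    m
  })
  gen <- build_generator(frozen, 4)
  expect_error(stationary_nullspace(gen), "reducible")
})

test_that("RK integration reaches the null-space solution", {
  model <- toy_model(0.4)
  N <- 30
  gen <- build_generator(model, N)
  st <- stationary_nullspace(gen)
  res <- integrate_to_stationarity(gen)
  expect_true(res$converged)
  expect_lt(res$residual, 1e-10)
  expect_lt(l1_distance(res$dist, st), 1e-7)
  expect_equal(sum(res$dist$prob), 1, tolerance = 1e-9)

  # an already-stationary initial condition is returned unchanged
  res0 <- integrate_to_stationarity(gen, rho0 = st)
  expect_true(res0$converged)
  expect_equal(nrow(res0$trace), 1)
  expect_lt(l1_distance(res0$dist, st), 1e-10)
})

test_that("RK integration agrees with an independent general-purpose integrator", {
  model <- toy_model(0.6)
  N <- 12
  gen <- build_generator(model, N)
  S <- gen$lattice$size
  y0 <- rep(1 / S, S)
  t_end <- 2
  ref <- deSolve::ode(y0, c(0, t_end),
                      function(t, y, p) list(as.vector(gen$W %*% y)),
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  mine <- suppressWarnings(
    integrate_to_stationarity(gen, t_max = t_end, stop_residual = 0,
                              snapshot_dt = t_end))
  expect_lt(sum(abs(mine$dist$prob - ref[2, -1])), 1e-7)
})

test_that("gillespie sampling is reproducible and converges to the stationary law", {
  # deterministic under a fixed seed
  d1 <- gillespie_sample(toy_model(0.4), 20, n_events = 2000, burn_in = 100,
                         seed = 99)
  d2 <- gillespie_sample(toy_model(0.4), 20, n_events = 2000, burn_in = 100,
                         seed = 99)
  expect_identical(d1$prob, d2$prob)

  # two-state chain: empirical occupancy near the hand-solved binomial;
  # per-state Monte Carlo error ~ (p(1-p)/n_eff)^{1/2} makes 0.05 a safe
  # a priori bound at this event budget
  emp <- gillespie_sample(two_state_model(1, 1), 2, n_events = 2e5,
                          burn_in = 1e3, seed = 7)
  expect_lt(sum(abs(emp$prob - c(1 / 4, 1 / 2, 1 / 4))), 0.05)
})

test_that("an absorbing state stops the simulation with a warning", {
  # pure drain toward state 1: once everything is in state 1 no move remains
  drain <- state_graph_model(2, function(x) matrix(c(0, 0, 1, 0), 2, 2))
  expect_warning(
    d <- gillespie_sample(drain, 3, n_events = 1e4, burn_in = 0, seed = 1),
    "absorbing")
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("relaxation rate recovers exponential decay and the spectral gap", {
  # pure synthetic exponential
  tr <- data.frame(time = seq(0, 5, by = 0.1))
  tr$distance <- exp(-3 * tr$time)
  expect_equal(relaxation_rate(tr, floor = 1e-12), 3, tolerance = 1e-6)

  expect_error(relaxation_rate(data.frame(time = 0:2, distance = rep(1e-12, 3))),
               "insufficient-data")

  # linear model: fitted rate equals the generator's spectral gap within 5%
  model <- random_linear_model(2, seed = 31)
  N <- 15
  gen <- build_generator(model, N)
  ev <- eigen(as.matrix(gen$W), only.values = TRUE)$values
  gap <- sort(abs(Re(ev)))[2]
  S <- gen$lattice$size
  set.seed(8)
  y0 <- stats::runif(S)
  res <- integrate_to_stationarity(
    gen, rho0 = lattice_distribution(gen$lattice, y0), snapshot_dt = 0.02)
  fitted <- relaxation_rate(res$trace, floor = 1e-7)
  expect_equal(fitted, gap, tolerance = 0.05)
})

test_that("probability is conserved along integrations", {
  gen <- build_generator(pdpc_model(pdpc_params(v2 = 2.0)), 15)
  res <- integrate_to_stationarity(gen)
  expect_equal(sum(res$dist$prob), 1, tolerance = 1e-9)
})
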