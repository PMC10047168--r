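test_that("laplacian matches hand assembly and conserves probability flux", {
  # two-state constant rates pi12 = pi21 = 1
  m2 <- two_state_model(1, 1)
  expect_equal(laplacian(m2, c(0.5, 0.5)),
               matrix(c(1, -1, -1, 1), 2, 2))

  # toy model, alpha = 0.5, x = (0.3, 0.4, 0.3): element-wise assembly from
  # the four rate formulas, theta(z) = 1 - alpha + alpha (1 - z)^2
  alpha <- 0.5
  theta <- function(z) 1 - alpha + alpha * (1 - z)^2
  x <- c(0.3, 0.4, 0.3)
  piAB <- 1; piBA <- theta(x[1]); piCB <- 1; piBC <- theta(x[3])
  L_hand <- matrix(0, 3, 3)
  L_hand[1, 2] <- -piAB; L_hand[2, 1] <- -piBA
  L_hand[3, 2] <- -piCB; L_hand[2, 3] <- -piBC
  diag(L_hand) <- c(piBA, piAB + piCB, piBC)
  expect_equal(laplacian(toy_model(alpha), x), L_hand, tolerance = 1e-14)

  # column sums vanish at machine precision across models and random points
  for (model in list(toy_model(0.7), pdpc_model(pdpc_params(v2 = 3)),
                     random_linear_model(4, seed = 7))) {
    pts <- random_simplex_points(10, model$M, seed = 11)
    for (r in seq_len(nrow(pts))) {
      expect_lt(max(abs(colSums(laplacian(model, pts[r, ])))), 1e-13)
    }
  }
})

test_that("laplacian rejects models returning negative rates", {
  bad <- state_graph_model(2, function(x) matrix(c(0, 1, 1, 0), 2, 2))
  bad$rates <- function(x) matrix(c(0, -1, 1, 0), 2, 2)
  expect_error(laplacian(bad, c(0.5, 0.5)), "negative")
})

test_that("null eigenvector: closed form, generic eigensolve and known cases agree", {
  # linear symmetric toy: all transitions equally likely
  expect_equal(null_eigenvector(toy_model(0), c(0.2, 0.5, 0.3)),
               rep(1 / 3, 3), tolerance = 1e-12)

  # two-state detailed balance: pi12 = 2, pi21 = 1 -> p = (2/3, 1/3)
  expect_equal(null_eigenvector(two_state_model(r12 = 2, r21 = 1), c(0.5, 0.5)),
               c(2 / 3, 1 / 3), tolerance = 1e-12)

  # three-state chain closed form vs a generic eigensolve of the Laplacian
  for (model in list(toy_model(0.6), pdpc_model(pdpc_params(v2 = 2.2)))) {
    pts <- random_simplex_points(25, 3, seed = 3)
    for (r in seq_len(nrow(pts))) {
      x <- pts[r, ]
      p <- null_eigenvector(model, x)
      L <- laplacian(model, x)
      e <- eigen(L)
      v <- Re(e$vectors[, which.min(abs(e$values))])
      v <- v / sum(v)
      expect_equal(p, v, tolerance = 1e-10)
      expect_lt(max(abs(L %*% p)), 1e-10)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("null eigenvector residual property holds on many random points", {
  model <- pdpc_model(pdpc_params(v2 = 2.8))
  pts <- random_simplex_points(100, 3, seed = 5)
  resid <- apply(pts, 1, function(x)
    max(abs(laplacian(model, x) %*% null_eigenvector(model, x))))
  expect_lt(max(resid), 1e-10)
})

test_that("disconnected rate graphs are reported as degenerate", {
  disc <- state_graph_model(4, function(x) {
    m <- matrix(0, 4, 4)
    m[1, 2] <- m[2, 1] <- 1  # component {1,2}
    m[3, 4] <- m[4, 3] <- 1  # component {3,4}
    m
  })
  expect_error(null_eigenvector(disc, rep(0.25, 4)), "disconnected")
})

test_that("deterministic flow conserves total density and vanishes at fixed points", {
  m <- toy_model(0)
  f <- deterministic_rhs(m, c(1, 0, 0))
  expect_equal(sum(f), 0, tolerance = 1e-14)
  expect_gt(f[2], 0)  # flow out of the pure-A corner toward the middle

  # at a self-consistent point the flow is zero
  expect_lt(max(abs(deterministic_rhs(m, rep(1 / 3, 3)))), 1e-12)

  # symmetric critical state of the cycle model zeroes the flow regardless
  # of the control parameter
  for (v2 in c(1.82, 3.04)) {
    x1 <- pdpc_critical_points(pdpc_params(v2 = v2))[[1]]
    expect_lt(max(abs(deterministic_rhs(pdpc_model(pdpc_params(v2 = v2)), x1))),
              1e-10)
  }
})

test_that("jacobian of p: linear models give zero, rows sum to zero, steps are consistent", {
  # constant rates: p does not depend on x
  J <- jacobian_p(random_linear_model(3, seed = 2), c(0.3, 0.3, 0.4))
  expect_lt(max(abs(J)), 1e-8)

  # normalization identity sum_k dp_k/dx_i = 0 at random points
  model <- toy_model(0.5)
  pts <- random_simplex_points(20, 3, seed = 9)
  for (r in seq_len(nrow(pts))) {
    J <- jacobian_p(model, pts[r, ])
    expect_lt(max(abs(rowSums(J))), 1e-6)
  }

  # Richardson consistency: halving the step changes nothing material
  x <- find_critical_points(toy_model(0.5), n_starts = 3, seed = 1)[[1]]$x_star
  J1 <- jacobian_p(toy_model(0.5), x, h = 1e-5)
  J2 <- jacobian_p(toy_model(0.5), x, h = 5e-6)
  expect_equal(J1, J2, tolerance = 1e-5)
})

test_that("critical point search finds, classifies and deduplicates fixed points", {
  # linear toy: unique stable point at the barycenter
  cps <- find_critical_points(toy_model(0), n_starts = 5, seed = 1)
  expect_length(cps, 1)
  expect_true(cps[[1]]$stable)
  expect_equal(cps[[1]]$x_star, rep(1 / 3, 3), tolerance = 1e-9)

  # bistable cycle: three points, symmetric one unstable, outer pair stable
  cps <- find_critical_points(pdpc_model(pdpc_params(v2 = 3.04)),
                              n_starts = 10, seed = 1)
  expect_length(cps, 3)
  stable <- vapply(cps, function(cp) cp$stable, logical(1))
  expect_equal(sum(stable), 2)
  analytic <- pdpc_critical_points(pdpc_params(v2 = 3.04))
  sym <- cps[[which(!stable)]]
  expect_equal(sym$x_star, analytic[[1]], tolerance = 1e-6)
  asym <- lapply(cps[stable], function(cp) cp$x_star)
  expect_equal(asym[[1]], rev(asym[[2]]), tolerance = 1e-9)  # mirror pair
  expect_true(any(vapply(analytic[-1], function(a)
    max(abs(a - asym[[1]])) < 1e-6, logical(1))))

  # monostable regime: single stable point equal to the symmetric state
  cps <- find_critical_points(pdpc_model(pdpc_params(v2 = 1.82)),
                              n_starts = 10, seed = 1)
  expect_length(cps, 1)
  expect_true(cps[[1]]$stable)
  expect_equal(cps[[1]]$x_star,
               pdpc_critical_points(pdpc_params(v2 = 1.82))[[1]],
               tolerance = 1e-9)

  # every reported point satisfies the self-consistency residual bound
  for (cp in cps) expect_lt(cp$residual, 1e-9)
})

test_that("bifurcation scan locates spectral crossings and handles flat families", {
  # linear family: indicator identically zero, no crossing
  expect_warning(
    scan <- bifurcation_scan(function(a) random_linear_model(3, seed = 4),
                             c(0, 0.5, 1)),
    "never crosses")
  expect_true(is.na(attr(scan, "crossing")))
  expect_lt(max(abs(scan$indicator)), 1e-8)

  # cycle model: crossing of 1 at the analytic threshold
  scan <- bifurcation_scan(function(v2) pdpc_model(pdpc_params(v2 = v2)),
                           seq(1.5, 3.5, by = 0.25))
  expect_equal(attr(scan, "crossing"), 2.5, tolerance = 1e-3)
})
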