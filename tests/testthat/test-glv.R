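# Fixed points, Jacobian abscissa, and the ODE oracle for the simple GLV case.

test_that("fixed_point solves w x* = -alpha with feasibility and stability info", {
  # identity fixture (not a valid topology, pure math check)
  fp <- fixed_point(-diag(3), alpha = 1)
  expect_equal(fp$x_star, rep(1, 3))
  expect_true(fp$feasible)
  expect_equal(fp$spectral_abscissa, -1, tolerance = 1e-12)

  # marginal 3-cycle fixture: off-diagonal -2, eigenvalues -1 - 2*omega over
  # cube roots of unity, max real part exactly 0 at x* = 1/3
  w <- diag(-1, 3)
  w[cbind(1:3, c(2, 3, 1))] <- -2
  fp <- fixed_point(w, alpha = 1)
  expect_equal(fp$x_star, rep(1 / 3, 3), tolerance = 1e-12)
  expect_lt(abs(fp$spectral_abscissa), 1e-10)

  ws <- rbind(c(-1, 2, 0), c(-1, 2, 0), c(0, 1, -1))
  expect_error(fixed_point(ws), "singular")
})

test_that("spectral_abscissa agrees with the characteristic-polynomial oracle (S <= 4)", {
  set.seed(21)
  for (rep in 1:100) {
    S <- sample(2:4, 1)
    w <- matrix(rnorm(S * S), S)
    x <- runif(S, 0.1, 2)
    expect_equal(spectral_abscissa(w, x),
                 oracle_abscissa_charpoly(x * w),
                 tolerance = 1e-8)
  }
})

test_that("uniform scaling of x* scales the abscissa linearly", {
  set.seed(5)
  w <- matrix(rnorm(25), 5)
  x <- runif(5, 0.2, 1)
  a1 <- spectral_abscissa(w, x)
  for (c in c(0.5, 2, 10))
    expect_equal(spectral_abscissa(w, c * x), c * a1, tolerance = 1e-10)
  expect_error(spectral_abscissa(w, c(x[-1], NA)), "non-finite")
})

test_that("integrate_glv confirms the linear stability classification", {
  topo <- fixture_cycle_topology(3)
  # stable: x* = 0.5 > x_c = 1/3
  w <- inverse_weights(topo, NULL, rep(0.5, 3), 1)
  out <- integrate_glv(w, 1, x0 = rep(0.5, 3) * 1.01, t_max = 200)
  expect_false(out$diverged)
  expect_equal(out$x_end, rep(0.5, 3), tolerance = 1e-6)

  # unstable: x* = 0.2 < 1/3; an asymmetric perturbation (the uniform
  # direction is a stable manifold of the cycle fixture) must not return
  wu <- inverse_weights(topo, NULL, rep(0.2, 3), 1)
  outu <- integrate_glv(wu, 1, x0 = rep(0.2, 3) * c(1.01, 0.995, 1.002),
                        t_max = 200)
  expect_true(outu$diverged || max(abs(outu$x_end - rep(0.2, 3))) > 1e-2)

  # starting exactly at the fixed point stays there
  out0 <- integrate_glv(w, 1, x0 = rep(0.5, 3), t_max = 50)
  expect_equal(out0$x_end, rep(0.5, 3), tolerance = 1e-8)
  expect_error(integrate_glv(w, 1, x0 = c(1, -1, 1)), "positive")
})

test_that("stability classification and ODE outcome agree on random fixtures", {
  set.seed(33)
  n_ok <- 0
  for (rep in 1:50) {
    S <- sample(3:6, 1)
    topo <- make_tree_like(S, sample(2:S, 1), seed = sample.int(1e6, 1))
    x_t <- rep(runif(1, 0.1, 0.9), S)
    w <- inverse_weights(topo, NULL, x_t, 1)
    s <- spectral_abscissa(w, x_t)
    if (abs(s) < 5e-3) next  # near-marginal: relaxation too slow for the oracle
    x0 <- x_t * (1 + runif(S, -0.003, 0.003))  # asymmetric perturbation
    out <- integrate_glv(w, 1, x0 = x0, t_max = 400)
    if (s < 0) {
      expect_false(out$diverged)
      expect_equal(out$x_end, x_t, tolerance = 1e-3)
    } else {
      expect_true(out$diverged || max(abs(out$x_end - x_t)) > 1e-3)
    }
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 40)  # the skip guard must not hollow out the property
})

test_that("interaction_matrix enforces the diagonal and mask invariants", {
  w <- diag(-1, 3)
  expect_s3_class(interaction_matrix(w), "interaction_matrix")
  wbad <- w; diag(wbad) <- -2
  expect_error(interaction_matrix(wbad), "diagonal")
  mask <- diag(3) > 0
  woff <- w; woff[1, 2] <- 0.5
  expect_error(interaction_matrix(woff, mask), "mask")
})
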