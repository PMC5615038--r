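# Inverse problem, marginal-stability scan, analytic loop oracle, and the
# explorability distributions.

test_that("inverse_weights reproduces the row formula and the fixed point", {
  topo <- fixture_cycle_topology(3)
  # x* = 1: tree weights vanish
  w1 <- inverse_weights(topo, NULL, rep(1, 3), 1)
  expect_equal(w1[cbind(1:3, topo$successor)], rep(0, 3))
  expect_equal(drop(w1 %*% rep(1, 3)), rep(-1, 3), ignore_attr = TRUE)
  # x* = 1/3: the marginal fixture with tree weights -2
  w3 <- inverse_weights(topo, NULL, rep(1 / 3, 3), 1)
  expect_equal(w3[cbind(1:3, topo$successor)], rep(-2, 3))
  # one extra link eps = 0.1 into row 1 at x* = 1/2
  ex <- extra_links(cbind(1L, 3L), 0.1, 3)
  we <- inverse_weights(topo, ex, rep(0.5, 3), 1)
  expect_equal(we[1, topo$successor[1]], (0.5 - 1 - 0.05) / 0.5)
  expect_equal(max(abs(we %*% rep(0.5, 3) + 1)), 0, tolerance = 1e-14)
  expect_error(inverse_weights(topo, NULL, c(1, 0, 1), 1), "non-zero")
})

test_that("inverse_weights then fixed_point round-trips arbitrary targets (property)", {
  set.seed(13)
  for (rep in 1:60) {
    S <- sample(3:15, 1)
    topo <- make_tree_like(S, sample(2:min(S, 6), 1), seed = sample.int(1e6, 1))
    ex <- add_random_links(topo, runif(1, 2 / S, 0.8), 0.2,
                           seed = sample.int(1e6, 1))
    x_t <- runif(S, 0.2, 2)
    alpha <- runif(S, 0.5, 1.5)
    w <- inverse_weights(topo, ex, x_t, alpha)
    expect_lt(max(abs(w %*% x_t + alpha)), 1e-12)
    fp <- fixed_point(w, alpha)
    expect_equal(fp$x_star, x_t, tolerance = 1e-8)
  }
})

test_that("homogeneous scan reproduces the analytic optimum V_E = 2/3 across sizes", {
  for (S in c(3, 5, 10, 20)) {
    topo <- make_tree_like(S, 3, seed = S)
    sc <- scan_marginal_homogeneous(topo)
    expect_true(sc$single_crossing)
    expect_equal(sc$x_c, 1 / 3, tolerance = 1e-5)
    expect_equal(sc$V_E, 2 / 3, tolerance = 1e-5)
  }
})

test_that("zero-weight extra links leave the scan unchanged", {
  topo <- make_tree_like(10, 3, seed = 2)
  ex <- add_random_links(topo, 0.5, 0.1, seed = 3)
  ex0 <- extra_links(ex$positions, rep(0, length(ex$weights)), 10)
  a <- scan_marginal_homogeneous(topo)
  b <- scan_marginal_homogeneous(topo, ex0)
  expect_equal(a$x_c, b$x_c, tolerance = 1e-9)
})

test_that("analytic loop formula matches numeric scans for L in 2..8 (oracle equivalence)", {
  set.seed(99)
  for (L in 2:8) {
    # independent numeric root-finder on an explicitly built cycle matrix
    expect_equal(oracle_xc_loop_numeric(L), analytic_xc_loop(L), tolerance = 1e-7)
    for (S in unique(c(L, L + 2, 12))) {
      if (S < L) next
      topo <- make_tree_like(S, L, seed = L * 100 + S)
      sc <- scan_marginal_homogeneous(topo)
      expect_true(sc$single_crossing)
      expect_equal(sc$x_c, analytic_xc_loop(L), tolerance = 1e-5)
    }
  }
  # the optimum is the 3-loop for every admissible size
  expect_equal(which.min(analytic_xc_loop(2:12)) + 1L, 3L)
  expect_error(analytic_xc_loop(1), "at least 2")
})

test_that("single-crossing classification brackets the marginal point", {
  topo <- make_tree_like(20, 3, seed = 8)
  seeds <- 1:20
  for (s in seeds) {
    ex <- add_random_links(topo, 0.5, 0.1, seed = s)
    sc <- scan_marginal_homogeneous(topo, ex)
    if (!sc$single_crossing) next
    w_lo <- inverse_weights(topo, ex, rep(sc$x_c - 1e-3, 20), 1)
    w_hi <- inverse_weights(topo, ex, rep(sc$x_c + 1e-3, 20), 1)
    expect_gt(spectral_abscissa(w_lo, rep(sc$x_c - 1e-3, 20)), 0)
    expect_lt(spectral_abscissa(w_hi, rep(sc$x_c + 1e-3, 20)), 0)
  }
})

test_that("explorability distribution: bare trees are degenerate at the loop value", {
  topo <- make_tree_like(12, 3, seed = 4)
  sm <- sample_explorability_distribution(topo, C = 2 / 12, n_realizations = 5,
                                          seed = 1)
  expect_equal(sm$fraction_single_crossing, 1)
  expect_equal(sm$mean_V_E, 2 / 3, tolerance = 1e-5)
  expect_equal(sd(sm$samples$V_E), 0, tolerance = 1e-12)
})

test_that("explorability distribution is seed-reproducible and sigma_eps-continuous", {
  topo <- make_tree_like(15, 3, seed = 4)
  a <- sample_explorability_distribution(topo, 0.4, 0.1, 20, seed = 77)
  b <- sample_explorability_distribution(topo, 0.4, 0.1, 20, seed = 77)
  expect_identical(a$samples, b$samples)
  # sigma_eps -> 0: V_E concentrates at the bare-tree value
  tiny <- sample_explorability_distribution(topo, 0.4, 1e-6, 20, seed = 78)
  expect_equal(tiny$mean_V_E, 2 / 3, tolerance = 1e-3)
  expect_lt(max(abs(tiny$samples$V_E - 2 / 3)), 1e-3)
})

test_that("heterogeneous sweep degenerates correctly and stays near 2/3 at sigma = 0.1", {
  topo <- make_tree_like(10, 3, seed = 6)
  het0 <- heterogeneity_config(sigma_alpha = 0, sigma_x = 0,
                               n_alpha_draws = 1, n_x_draws = 1)
  d0 <- explorability_heterogeneous(topo, het = het0, seed = 1)
  expect_gt(nrow(d0), 0)
  # with no jitter, edge points cluster at the homogeneous V_E = 2/3 within
  # the spread induced by edge_tolerance on the grid
  expect_lt(max(abs(d0$V_E - 2 / 3)), 0.05)

  het <- heterogeneity_config(sigma_alpha = 0.1, sigma_x = 0.1,
                              n_alpha_draws = 5, n_x_draws = 5)
  d <- explorability_heterogeneous(topo, het = het, seed = 2)
  expect_gt(nrow(d), 0)
  expect_lt(abs(mean(d$V_E) - 2 / 3), 0.1)

  # a vanishing tolerance admits (almost surely) no grid point
  het_tiny <- heterogeneity_config(sigma_alpha = 0.1, sigma_x = 0.1,
                                   edge_tolerance = 1e-12,
                                   n_alpha_draws = 2, n_x_draws = 2)
  expect_equal(nrow(explorability_heterogeneous(topo, het = het_tiny, seed = 3)), 0)
})
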