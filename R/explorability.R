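# Explorability: the volume of feasible, stable fixed points reachable by
# tuning the tree-link weights while the extra-link weights eps_ij stay
# fixed. In the homogeneous reduction (x*_i = x*, alpha_i = alpha) almost all
# realizations show a two-region structure along x*: unstable below a single
# marginal abundance x_c, stable above. V_E = V_0 - x_c (with V_0 = 1) is the
# explorability proxy.

#' Default homogeneous scan grid
#'
#' Grid of homogeneous abundances x* over `(0, V_0]` used to locate the
#' marginal-stability crossing; the crossing is then refined by bisection.
#'
#' @param n Number of grid points.
#' @param lo,hi Grid range; `lo` must be > 0 (feasibility).
#' @return Increasing numeric vector.
#' @export
explorability_grid <- function(n = 200, lo = 1e-3, hi = 1) {
  stopifnot(lo > 0, hi > lo, n >= 10)
  seq(lo, hi, length.out = n)
}

#' Recover interaction weights from a target fixed point
#'
#' The inverse problem: given the topology, the fixed extra-link weights, the
#' growth rates and a target equilibrium `x*`, solve row-wise for the single
#' tunable (tree) weight of each row so that `w x* = -alpha` holds exactly:
#' `w[i, sigma(i)] = (x*_i - alpha_i - sum_extra eps_ij x*_j) / x*_sigma(i)`.
#'
#' @param topo A [tree_topology()].
#' @param extra An [extra_links()] set (or `NULL` for none).
#' @param x_star Target fixed point; all components non-zero.
#' @param alpha Growth rates, scalar or length-`S` vector (default 1).
#' @return An [interaction_matrix()] satisfying `w x* = -alpha`.
#' @examples
#' topo <- make_tree_like(3, loop_length = 3, seed = 1)
#' w <- inverse_weights(topo, NULL, rep(1/3, 3), alpha = 1)
#' max(abs(w %*% rep(1/3, 3) + 1))  # 0: x* is the fixed point
#' @export
inverse_weights <- function(topo, extra = NULL, x_star, alpha = 1) {
  S <- topo$n_nodes
  if (is.null(extra)) extra <- no_extra_links(S)
  x_star <- as.numeric(x_star)
  if (length(x_star) != S) stop("x_star must have length S", call. = FALSE)
  if (any(x_star == 0))
    stop("x_star components must be non-zero (row formula divides by x*_sigma(i))",
         call. = FALSE)
  alpha <- rep_len(as.numeric(alpha), S)
  w <- diag(-1, S)
  if (nrow(extra$positions)) w[extra$positions] <- extra$weights
  # per-row contribution of the fixed extra links to sum_j w_ij x*_j
  eps_dot_x <- numeric(S)
  if (nrow(extra$positions)) {
    contrib <- extra$weights * x_star[extra$positions[, 2]]
    agg <- tapply(contrib, extra$positions[, 1], sum)
    eps_dot_x[as.integer(names(agg))] <- agg
  }
  w[cbind(seq_len(S), topo$successor)] <-
    (x_star - alpha - eps_dot_x) / x_star[topo$successor]
  interaction_matrix(w)
}

# Fast homogeneous weight builder: for x*_i = x and alpha_i = alpha, row i's
# tree weight reduces to 1 - alpha/x - e_i with e_i the row sum of the extra
# weights, so the scan only rewrites S entries per grid point.
homogeneous_weight_closure <- function(topo, extra, alpha_value) {
  S <- topo$n_nodes
  base <- diag(-1, S)
  e_row <- numeric(S)
  if (!is.null(extra) && nrow(extra$positions)) {
    base[extra$positions] <- extra$weights
    for (k in seq_along(extra$weights))
      e_row[extra$positions[k, 1]] <- e_row[extra$positions[k, 1]] + extra$weights[k]
  }
  tree_idx <- cbind(seq_len(S), topo$successor)
  function(x) {
    w <- base
    w[tree_idx] <- 1 - alpha_value / x - e_row
    w
  }
}

#' Locate the marginal-stability crossing along homogeneous fixed points
#'
#' Sweeps the homogeneous abundance `x*` over `grid`, building the weight
#' matrix by the inverse problem at each point and evaluating the spectral
#' abscissa of the Jacobian `J = x* w`. If the sign pattern is
#' unstable-below / stable-above with a single crossing, the marginal
#' abundance `x_c` is refined by bisection (to `refine_tol` in `x`) and the
#' explorability `V_E = V_0 - x_c` is returned.
#'
#' @param topo A [tree_topology()].
#' @param extra Optional [extra_links()].
#' @param alpha_value Homogeneous growth rate (default 1).
#' @param grid Scan grid from [explorability_grid()].
#' @param V0 Reference constant of the explorability proxy (default 1).
#' @param refine_tol Bisection tolerance on `x_c`.
#' @return An object of class `explorability_result`: list with
#'   `single_crossing`, `x_c`, `V_E`, `V0`, `abscissas` (Jacobian abscissa at
#'   each grid point), `grid`.
#' @examples
#' topo <- make_tree_like(5, loop_length = 3, seed = 1)
#' scan_marginal_homogeneous(topo)$V_E  # 2/3: the optimal tree-like value
#' @export
scan_marginal_homogeneous <- function(topo, extra = NULL, alpha_value = 1,
                                      grid = explorability_grid(), V0 = 1,
                                      refine_tol = 1e-6) {
  stopifnot(alpha_value > 0)
  wfun <- homogeneous_weight_closure(topo, extra, alpha_value)
  # sign of the J = x*w abscissa equals the sign of the w abscissa for x > 0
  s_w <- vapply(grid, function(x)
    max(Re(eigen(wfun(x), only.values = TRUE)$values)), numeric(1))
  s_J <- grid * s_w
  n <- length(grid)
  k <- if (s_w[1] > 0) max(which(s_w > 0)) else 0L
  single <- k >= 1L && k < n && all(s_w[seq_len(k)] > 0) && all(s_w[(k + 1):n] <= 0)
  res <- list(single_crossing = single, x_c = NA_real_, V_E = NA_real_,
              V0 = V0, abscissas = s_J, grid = grid)
  if (single) {
    lo <- grid[k]; hi <- grid[k + 1]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      s <- max(Re(eigen(wfun(mid), only.values = TRUE)$values))
      if (s > 0) lo <- mid else hi <- mid
    }
    res$x_c <- (lo + hi) / 2
    res$V_E <- V0 - res$x_c
  }
  structure(res, class = "explorability_result")
}

#' @export
print.explorability_result <- function(x, ...) {
  if (x$single_crossing)
    cat(sprintf("Single marginal crossing at x_c = %.6f; V_E = %.6f (V0 = %g)\n",
                x$x_c, x$V_E, x$V0))
  else
    cat("No single unstable-below/stable-above crossing on the scan grid\n")
  invisible(x)
}

#' Closed-form marginal abundance of a bare loop topology
#'
#' For a tree-like network whose cycle has length `L` (and alpha = 1, V0 = 1)
#' the non-trivial eigenvalues of `w` are `-1 + a * omega` over the `L`-th
#' roots of unity `omega`, with `a = 1 - 1/x*` the common tree weight. The
#' marginal abundance is `1/2` for even `L` and `cos(pi/L)/(1 + cos(pi/L))`
#' for odd `L`; the minimum over `L` (hence maximal explorability
#' `V_E = 2/3`) is at `L = 3`.
#'
#' @param L Loop length, `L >= 2`.
#' @return The marginal homogeneous abundance `x_c`.
#' @export
analytic_xc_loop <- function(L) {
  L <- as.integer(L)
  if (any(L < 2L)) stop("loop length must be at least 2", call. = FALSE)
  ifelse(L %% 2L == 0L, 0.5, cos(pi / L) / (1 + cos(pi / L)))
}

#' Sample the explorability distribution at fixed connectivity
#'
#' Draws `n_realizations` independent extra-link configurations (uniform
#' random locations, Gaussian weights) on top of the base topology, runs the
#' homogeneous marginal scan for each, and collects `V_E` over the
#' realizations with the single-crossing structure. Realizations without it
#' are excluded from the `V_E` sample but counted in the reported fraction.
#'
#' @param topo Base [tree_topology()].
#' @param C Target connectivity (>= `2/S`).
#' @param sigma_eps Std of the Gaussian extra-link weights.
#' @param n_realizations Number of extra-link configurations.
#' @param seed Optional root seed; child seeds are split per realization.
#' @param grid Scan grid.
#' @param alpha_value Homogeneous growth rate.
#' @return An object of class `explorability_sample`: list with `samples`
#'   (data.frame: realization_id, C, sigma_eps, x_c, V_E, single_crossing),
#'   `fraction_single_crossing`, `mean_V_E`, `se_V_E`.
#' @export
sample_explorability_distribution <- function(topo, C, sigma_eps = 0.1,
                                              n_realizations = 1000,
                                              seed = NULL,
                                              grid = explorability_grid(),
                                              alpha_value = 1) {
  stopifnot(n_realizations >= 1)
  seeds <- derive_seeds(seed, n_realizations)
  rows <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    ex <- add_random_links(topo, C, sigma_eps, seed = seeds[r])
    sc <- scan_marginal_homogeneous(topo, ex, alpha_value, grid)
    rows[[r]] <- data.frame(realization_id = r, C = C, sigma_eps = sigma_eps,
                            x_c = sc$x_c, V_E = sc$V_E,
                            single_crossing = sc$single_crossing)
  }
  samples <- do.call(rbind, rows)
  ok <- samples$single_crossing
  structure(
    list(samples = samples,
         fraction_single_crossing = mean(ok),
         mean_V_E = if (any(ok)) mean(samples$V_E[ok]) else NA_real_,
         se_V_E = if (sum(ok) > 1) stats::sd(samples$V_E[ok]) / sqrt(sum(ok))
                  else NA_real_,
         C = C, sigma_eps = sigma_eps, n_realizations = n_realizations),
    class = "explorability_sample"
  )
}

#' @export
print.explorability_sample <- function(x, ...) {
  cat(sprintf("Explorability sample: C = %.3g, n = %d, single-crossing %.1f%%, mean V_E = %.4f\n",
              x$C, x$n_realizations, 100 * x$fraction_single_crossing, x$mean_V_E))
  invisible(x)
}

#' Heterogeneity settings for the explorability sweep
#'
#' Jitter configuration for the heterogeneous explorability estimate:
#' growth rates `alpha_i = alpha + q_i` and fixed points `x*_i = x* + p_i`
#' with `q_i ~ N(0, sigma_alpha^2)`, `p_i ~ N(0, sigma_x^2)`. A grid point is
#' kept as "edge of stability" when `|Re(lambda)_max| < edge_tolerance`.
#'
#' @param sigma_alpha Std of growth-rate jitter.
#' @param sigma_x Std of fixed-point jitter.
#' @param edge_tolerance Threshold on the absolute Jacobian abscissa
#'   (default 1e-2).
#' @param n_alpha_draws,n_x_draws Numbers of `q` and `p` draws.
#' @return An object of class `heterogeneity_config`.
#' @export
heterogeneity_config <- function(sigma_alpha = 0.1, sigma_x = 0.1,
                                 edge_tolerance = 1e-2,
                                 n_alpha_draws = 10, n_x_draws = 10) {
  stopifnot(sigma_alpha >= 0, sigma_x >= 0, edge_tolerance > 0,
            n_alpha_draws >= 1, n_x_draws >= 1)
  structure(list(sigma_alpha = sigma_alpha, sigma_x = sigma_x,
                 edge_tolerance = edge_tolerance,
                 n_alpha_draws = as.integer(n_alpha_draws),
                 n_x_draws = as.integer(n_x_draws)),
            class = "heterogeneity_config")
}

#' Explorability samples under heterogeneous abundances and growth rates
#'
#' For each draw of growth-rate jitter `q` and fixed-point jitter `p`
#' (held fixed within a sweep), the base abundance `x*` moves over `grid`;
#' every feasible grid point whose Jacobian abscissa lies within
#' `edge_tolerance` of zero is recorded as an edge-of-stability point with
#' `V_E = 1 - sum_i x*_i / S`.
#'
#' @param topo A [tree_topology()].
#' @param extra Optional [extra_links()].
#' @param het A [heterogeneity_config()].
#' @param grid Base-abundance grid.
#' @param seed Optional seed.
#' @param alpha_value Mean growth rate (default 1).
#' @return Data frame with columns `q_draw`, `p_draw`, `x_base`, `abscissa`,
#'   `V_E`.
#' @export
explorability_heterogeneous <- function(topo, extra = NULL,
                                        het = heterogeneity_config(),
                                        grid = explorability_grid(),
                                        seed = NULL, alpha_value = 1) {
  S <- topo$n_nodes
  with_seed(seed, {
    out <- list()
    for (iq in seq_len(het$n_alpha_draws)) {
      q <- stats::rnorm(S, 0, het$sigma_alpha)
      alpha_vec <- alpha_value + q
      for (ip in seq_len(het$n_x_draws)) {
        p <- stats::rnorm(S, 0, het$sigma_x)
        for (x0 in grid) {
          xv <- x0 + p
          if (any(xv <= 0)) next  # infeasible point: outside the scanned set
          w <- inverse_weights(topo, extra, xv, alpha_vec)
          s <- spectral_abscissa(w, xv)
          if (abs(s) < het$edge_tolerance)
            out[[length(out) + 1L]] <-
              data.frame(q_draw = iq, p_draw = ip, x_base = x0,
                         abscissa = s, V_E = 1 - sum(xv) / S)
        }
      }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(q_draw = integer(0), p_draw = integer(0),
                    x_base = numeric(0), abscissa = numeric(0),
                    V_E = numeric(0))
  })
}
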