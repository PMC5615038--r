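# Dynamical robustness: perturb the dynamics itself, (G + dG)(F + dF),
# rather than the state. At the new stationary point the Jacobian keeps the
# reduced form J'_ij = xi'_i w_ij, with xi' a random vector summarizing the
# perturbation. Starting from the worst case -- a matrix at the edge of
# stability, w^edge, whose abscissa is exactly zero -- the statistic
# R = -(5th percentile of Re(lambda')_max) measures how much stability is
# typically gained under random perturbations.

#' Edge-of-stability interaction matrix
#'
#' Builds the interaction matrix whose homogeneous fixed point sits exactly
#' at the marginal abundance `x_c` found by [scan_marginal_homogeneous()]:
#' its Jacobian abscissa is zero to within the scan's bisection tolerance.
#'
#' @param topo A [tree_topology()].
#' @param extra Optional [extra_links()].
#' @param alpha_value Homogeneous growth rate.
#' @param grid Scan grid.
#' @return An object of class `edge_matrix`: list with `weights`
#'   (an [interaction_matrix()]), `x_edge` (marginal abundance) and
#'   `abscissa` (residual abscissa at `x_edge`).
#' @examples
#' topo <- make_tree_like(4, loop_length = 3, seed = 1)
#' em <- edge_matrix(topo)      # tree weights -2 at x_c = 1/3
#' em$abscissa                  # ~0
#' @export
edge_matrix <- function(topo, extra = NULL, alpha_value = 1,
                        grid = explorability_grid()) {
  sc <- scan_marginal_homogeneous(topo, extra, alpha_value, grid)
  if (!sc$single_crossing)
    stop("no single marginal crossing: edge matrix undefined for this realization",
         call. = FALSE)
  x_edge <- rep(sc$x_c, topo$n_nodes)
  w <- inverse_weights(topo, extra, x_edge, alpha_value)
  structure(list(weights = w, x_edge = sc$x_c,
                 abscissa = spectral_abscissa(w, x_edge)),
            class = "edge_matrix")
}

#' Spectral abscissa of the perturbed Jacobian
#'
#' Evaluates `max Re(lambda)` of `J'_ij = xi'_i w^edge_ij`, the reduced
#' Jacobian form at the stationary point of the perturbed dynamics.
#'
#' @param edge An [edge_matrix()].
#' @param xi Perturbation vector `xi'` of length `S` (finite).
#' @return The perturbed spectral abscissa.
#' @export
perturbed_abscissa <- function(edge, xi) {
  spectral_abscissa(edge$weights, xi)
}

#' Robustness statistic from a sample of perturbed abscissas
#'
#' `R = -(p-th percentile)` of the empirical distribution of
#' `Re(lambda')_max`, with linear interpolation between order statistics
#' (R's default quantile type 7). Lower percentiles emphasize the worst
#' cases; the default is the 5th.
#'
#' @param abscissas Non-empty numeric vector of perturbed abscissas.
#' @param percentile Percentile in (0, 100); default 5.
#' @return The robustness statistic `R`.
#' @export
robustness_R <- function(abscissas, percentile = 5) {
  if (length(abscissas) == 0) stop("empty abscissa sample", call. = FALSE)
  if (!all(is.finite(abscissas))) stop("non-finite abscissas", call. = FALSE)
  -unname(stats::quantile(abscissas, percentile / 100, type = 7))
}

#' Sample the dynamical-robustness distribution at fixed connectivity
#'
#' For each of `n_eps` extra-link configurations admitting an edge matrix,
#' draws `n_xi` perturbation vectors `xi'` with i.i.d. components uniform on
#' `[0, 1]` and collects the perturbed abscissas; the pooled distribution
#' yields `R`. Configurations without a single marginal crossing are skipped
#' and counted in `n_skipped`.
#'
#' @param topo Base [tree_topology()].
#' @param C Target connectivity.
#' @param sigma_eps Std of the extra-link weights.
#' @param n_eps Number of extra-link configurations.
#' @param n_xi Number of `xi'` draws per configuration.
#' @param seed Optional root seed (split per configuration).
#' @param percentile Percentile for `R` (default 5).
#' @param grid Scan grid for the edge matrices.
#' @param alpha_value Homogeneous growth rate.
#' @return An object of class `robustness_sample`: list with `abscissas`
#'   (data.frame: eps_id, xi_id, C, abscissa), `R`, `percentile`,
#'   `n_skipped`, `skip_rate`.
#' @export
sample_robustness_distribution <- function(topo, C, sigma_eps = 0.1,
                                           n_eps = 100, n_xi = 100,
                                           seed = NULL, percentile = 5,
                                           grid = explorability_grid(),
                                           alpha_value = 1) {
  stopifnot(n_eps >= 1, n_xi >= 1)
  S <- topo$n_nodes
  seeds <- derive_seeds(seed, 2L * n_eps)  # one stream for eps, one for xi
  rows <- vector("list", n_eps)
  n_skipped <- 0L
  for (r in seq_len(n_eps)) {
    ex <- add_random_links(topo, C, sigma_eps, seed = seeds[2L * r - 1L])
    em <- tryCatch(edge_matrix(topo, ex, alpha_value, grid),
                   error = function(e) NULL)
    if (is.null(em)) {
      n_skipped <- n_skipped + 1L
      next
    }
    absc <- with_seed(seeds[2L * r], {
      xi_mat <- matrix(stats::runif(n_xi * S), n_xi, S)
      apply(xi_mat, 1, function(xi) perturbed_abscissa(em, xi))
    })
    rows[[r]] <- data.frame(eps_id = r, xi_id = seq_len(n_xi), C = C,
                            abscissa = absc)
  }
  abscissas <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(abscissas))
    stop("no extra-link configuration admitted an edge matrix", call. = FALSE)
  structure(
    list(abscissas = abscissas,
         R = robustness_R(abscissas$abscissa, percentile),
         percentile = percentile, C = C, sigma_eps = sigma_eps,
         n_eps = n_eps, n_xi = n_xi, n_skipped = n_skipped,
         skip_rate = n_skipped / n_eps),
    class = "robustness_sample"
  )
}

#' @export
print.robustness_sample <- function(x, ...) {
  cat(sprintf("Robustness sample: C = %.3g, R(%d%%) = %.4f, %d/%d configs skipped\n",
              x$C, x$percentile, x$R, x$n_skipped, x$n_eps))
  invisible(x)
}
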