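# Stochastic hill climbing of the fixed extra-link weights eps_ij. Link
# locations stay fixed; every step perturbs all weights at once with
# Gaussian noise of std delta_eps and accepts the proposal only if the
# optimized quantity strictly increases. Multi-objective mode accepts only
# if explorability and robustness both increase; alternating mode optimizes
# one quantity at a time in fixed-length periods.

#' Hill-climbing configuration
#'
#' @param objective One of `"explorability"`, `"robustness"`, `"both"`,
#'   `"alternating"`.
#' @param steps Number of iterations `T` (default 200).
#' @param step_std Proposal std `delta_eps` (default 0.01); must lie in
#'   `[1e-3, 1e-1]`, the range over which the results are insensitive to it.
#' @param seed Optional integer seed.
#' @param n_xi Number of perturbation vectors used for the in-loop robustness
#'   objective (common random numbers, drawn once per run).
#' @param alternating_period Period length (steps) for `"alternating"` mode.
#' @param percentile Percentile for the robustness statistic.
#' @param grid Homogeneous scan grid for the objective evaluations.
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(objective = c("explorability", "robustness",
                                              "both", "alternating"),
                                steps = 200, step_std = 0.01, seed = NULL,
                                n_xi = 200, alternating_period = 20,
                                percentile = 5,
                                grid = explorability_grid()) {
  objective <- match.arg(objective)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  # 0 is allowed as the degenerate no-move proposal; positive values must lie
  # in the range over which results are insensitive to the choice
  if (step_std != 0 && (step_std < 1e-3 || step_std > 1e-1))
    stop("step_std (delta_eps) must be 0 or lie in [1e-3, 1e-1]", call. = FALSE)
  if (alternating_period < 1) stop("alternating_period must be >= 1", call. = FALSE)
  structure(list(objective = objective, steps = as.integer(steps),
                 step_std = step_std, seed = seed, n_xi = as.integer(n_xi),
                 alternating_period = as.integer(alternating_period),
                 percentile = percentile, grid = grid),
            class = "optimization_config")
}

# Deterministic objective evaluator for a fixed xi panel (common random
# numbers): V_E from the homogeneous scan; R from the edge matrix under the
# shared xi draws, computed only when requested (it dominates the step cost).
# NA with attribute "defined" = FALSE signals no single crossing.
make_objective_eval <- function(topo, positions, cfg, xi_mat) {
  S <- topo$n_nodes
  function(weights, need_R) {
    ex <- extra_links(positions, weights, S)
    sc <- scan_marginal_homogeneous(topo, ex, 1, cfg$grid)
    if (!sc$single_crossing)
      return(c(V_E = NA_real_, R = NA_real_))
    R <- NA_real_
    if (need_R) {
      w_edge <- inverse_weights(topo, ex, rep(sc$x_c, S), 1)
      absc <- apply(xi_mat, 1, function(xi) spectral_abscissa(w_edge, xi))
      R <- robustness_R(absc, cfg$percentile)
    }
    c(V_E = sc$V_E, R = R)
  }
}

climb_engine <- function(topo, extra0, cfg) {
  S <- topo$n_nodes
  m <- length(extra0$weights)
  if (m == 0L)
    stop("hill climbing needs at least one tunable extra link", call. = FALSE)
  with_seed(cfg$seed, {
    xi_mat <- matrix(stats::runif(cfg$n_xi * S), cfg$n_xi, S)
    evaluate <- make_objective_eval(topo, extra0$positions, cfg, xi_mat)
    cur_w <- extra0$weights
    cur <- c(V_E = NA_real_, R = NA_real_)
    # which components of `cur` have been evaluated for cur_w (an NA value
    # with computed = TRUE means the objective is genuinely undefined there)
    computed <- c(V_E = FALSE, R = FALSE)
    trace <- data.frame(step = seq_len(cfg$steps), proposed_norm = NA_real_,
                        accepted = FALSE, V_E = NA_real_, R = NA_real_)
    for (t in seq_len(cfg$steps)) {
      active <- switch(cfg$objective,
        explorability = "V_E",
        robustness = "R",
        both = c("V_E", "R"),
        alternating = if (((t - 1L) %/% cfg$alternating_period) %% 2L == 0L)
          "V_E" else "R")
      need_R <- "R" %in% active
      if (any(!computed[active])) {
        cur <- evaluate(cur_w, need_R)
        computed["V_E"] <- TRUE
        computed["R"] <- need_R
      }
      dw <- stats::rnorm(m, 0, cfg$step_std)
      prop_w <- cur_w + dw
      trace$proposed_norm[t] <- sqrt(sum(dw^2))
      prop <- evaluate(prop_w, need_R)
      cur_cmp <- ifelse(is.na(cur), -Inf, cur)  # undefined never blocks progress
      ok <- !anyNA(prop[active]) && all(prop[active] > cur_cmp[active])
      if (ok) {
        cur_w <- prop_w
        cur <- prop
        computed["V_E"] <- TRUE
        computed["R"] <- need_R
      }
      trace$accepted[t] <- ok
      trace$V_E[t] <- cur[["V_E"]]
      trace$R[t] <- cur[["R"]]
    }
    final <- evaluate(cur_w, TRUE)
    structure(
      list(trace = trace,
           final_extra = extra_links(extra0$positions, cur_w, S),
           initial_extra = extra0,
           final = final, config = cfg,
           acceptance_rate = mean(trace$accepted)),
      class = "optimization_trace"
    )
  })
}

#' Single-objective stochastic hill climbing
#'
#' Optimizes either the explorability `V_E` or the robustness `R` over the
#' extra-link weights, locations fixed. A proposal perturbs every weight by
#' `Normal(0, step_std^2)` and is accepted iff the objective strictly
#' increases; proposals whose objective is undefined (no single crossing) are
#' rejected. The robustness objective is made deterministic within a run by
#' drawing the `xi'` panel once (common random numbers).
#'
#' @param topo A [tree_topology()].
#' @param extra0 Initial [extra_links()] (at least one link).
#' @param cfg An [optimization_config()] with objective `"explorability"` or
#'   `"robustness"`.
#' @return An object of class `optimization_trace`: list with `trace`
#'   (data.frame: step, accepted, V_E, R), `final_extra`, `final`,
#'   `acceptance_rate`.
#' @export
hill_climb <- function(topo, extra0, cfg) {
  if (!cfg$objective %in% c("explorability", "robustness"))
    stop("hill_climb handles single objectives; use multi_objective_climb",
         call. = FALSE)
  climb_engine(topo, extra0, cfg)
}

#' Multi-objective hill climbing
#'
#' Mode `"both"` accepts a proposal only when explorability and robustness
#' both strictly increase; mode `"alternating"` optimizes one quantity at a
#' time in periods of `alternating_period` steps.
#'
#' @inheritParams hill_climb
#' @param cfg An [optimization_config()] with objective `"both"` or
#'   `"alternating"`.
#' @return An `optimization_trace` (see [hill_climb()]).
#' @export
multi_objective_climb <- function(topo, extra0, cfg) {
  if (!cfg$objective %in% c("both", "alternating"))
    stop("multi_objective_climb requires objective 'both' or 'alternating'",
         call. = FALSE)
  climb_engine(topo, extra0, cfg)
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("Hill climb (%s): %d steps, %.1f%% accepted, final V_E = %.4f, R = %.4f\n",
              x$config$objective, nrow(x$trace), 100 * x$acceptance_rate,
              x$final[["V_E"]], x$final[["R"]]))
  invisible(x)
}
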