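# GLV core: fixed points, Jacobians and spectral abscissa for the simple
# generalized Lotka-Volterra case  dx_i/dt = x_i (alpha_i + sum_j w_ij x_j).
# The Jacobian at a fixed point x* is J_ij = x*_i w_ij; local stability holds
# iff its spectral abscissa (max real part of the eigenvalues) is negative.

#' Interaction matrix with fixed self-interactions
#'
#' Validates and tags an `S x S` weight matrix `w`: the diagonal is fixed at
#' -1 (setting the scale of interaction strengths) and entries outside the
#' adjacency mask must be zero.
#'
#' @param weights Numeric `S x S` matrix.
#' @param mask Optional logical `S x S` adjacency mask; if supplied,
#'   off-mask entries of `weights` must be zero.
#' @return The weight matrix with class `interaction_matrix`.
#' @export
interaction_matrix <- function(weights, mask = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (!all(is.finite(weights)))
    stop("interaction weights must be finite", call. = FALSE)
  if (any(abs(diag(weights) + 1) > 1e-12))
    stop("diagonal entries must equal -1", call. = FALSE)
  if (!is.null(mask) && any(weights[!mask] != 0))
    stop("non-zero weight outside the adjacency mask", call. = FALSE)
  structure(weights, class = c("interaction_matrix", "matrix"))
}

#' Spectral abscissa of the GLV Jacobian
#'
#' Returns `max_i Re(lambda_i)` of `J_ij = x*_i w_ij`, the Jacobian of the
#' simple GLV dynamics at the fixed point `x_star`. Negative means the fixed
#' point is locally stable.
#'
#' @param w Numeric `S x S` weight matrix.
#' @param x_star Numeric state vector of length `S`.
#' @return The largest real part among the eigenvalues of `diag(x_star) %*% w`.
#' @export
spectral_abscissa <- function(w, x_star) {
  if (!all(is.finite(w)) || !all(is.finite(x_star)))
    stop("non-finite input to spectral_abscissa", call. = FALSE)
  if (length(x_star) != nrow(w))
    stop("length(x_star) must match nrow(w)", call. = FALSE)
  # column-major recycling: x_star * w scales row i by x_star[i]
  max(Re(eigen(x_star * unclass(w), only.values = TRUE)$values))
}

#' Fixed point of the simple GLV dynamics
#'
#' Solves `w x* = -alpha` for the non-trivial stationary point
#' `x* = -w^{-1} alpha`, flags feasibility (all components strictly
#' positive), and evaluates the spectral abscissa of the Jacobian there.
#'
#' @param w Numeric `S x S` weight matrix (diagonal -1).
#' @param alpha Growth rates: scalar (recycled) or length-`S` vector.
#'   Defaults to 1.
#' @param kappa_max Condition-number cap above which `w` is treated as
#'   numerically singular.
#' @return An object of class `glv_fixed_point`: list with `x_star`,
#'   `feasible`, `spectral_abscissa`, `residual`.
#' @examples
#' w <- -diag(3)
#' fixed_point(w, alpha = 1)$x_star  # c(1, 1, 1)
#' @export
fixed_point <- function(w, alpha = 1, kappa_max = 1e12) {
  S <- nrow(w)
  alpha <- rep_len(as.numeric(alpha), S)
  kap <- kappa(unclass(w), exact = FALSE)
  if (!is.finite(kap) || kap > kappa_max)
    stop(sprintf("interaction matrix numerically singular (condition estimate %.3g)", kap),
         call. = FALSE)
  x <- drop(solve(unclass(w), -alpha))
  res <- max(abs(unclass(w) %*% x + alpha))
  if (res > 1e-10 * max(abs(alpha)))
    stop(sprintf("fixed-point residual %.3g exceeds tolerance", res), call. = FALSE)
  structure(
    list(x_star = x,
         feasible = all(x > 0),
         spectral_abscissa = spectral_abscissa(w, x),
         residual = res),
    class = "glv_fixed_point"
  )
}

#' @export
print.glv_fixed_point <- function(x, ...) {
  cat(sprintf("GLV fixed point (S = %d): %s, spectral abscissa %.4g\n",
              length(x$x_star),
              if (x$feasible) "feasible" else "not feasible",
              x$spectral_abscissa))
  invisible(x)
}

#' Integrate the simple GLV dynamics
#'
#' Adaptive step-doubling RK4 integration of
#' `dx_i/dt = x_i (alpha_i + sum_j w_ij x_j)`. This is a validation oracle
#' for the linear stability classification, not a production integrator: when
#' the spectral abscissa at `x*` is negative and `x0` starts near `x*`, the
#' trajectory must end near `x*`.
#'
#' @param w Numeric `S x S` weight matrix.
#' @param alpha Growth rates (scalar or vector).
#' @param x0 Strictly positive initial state.
#' @param t_max Integration horizon.
#' @param abs_tol Local error tolerance for step adaptation.
#' @param blowup_cap Any component exceeding this flags divergence.
#' @return List with `x_end`, `diverged` (logical), `t_end`.
#' @export
integrate_glv <- function(w, alpha = 1, x0, t_max = 100, abs_tol = 1e-9,
                          blowup_cap = 1e6) {
  S <- nrow(w)
  alpha <- rep_len(as.numeric(alpha), S)
  if (any(x0 <= 0)) stop("x0 must be strictly positive", call. = FALSE)
  w <- unclass(w)
  deriv <- function(x) x * (alpha + drop(w %*% x))
  rk4 <- function(x, h) {
    k1 <- deriv(x)
    k2 <- deriv(x + h / 2 * k1)
    k3 <- deriv(x + h / 2 * k2)
    k4 <- deriv(x + h * k3)
    x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  t <- 0
  h <- min(0.01, t_max)
  x <- as.numeric(x0)
  while (t < t_max) {
    h <- min(h, t_max - t)
    big <- rk4(x, h)
    small <- rk4(rk4(x, h / 2), h / 2)
    err <- max(abs(big - small))
    if (is.finite(err) && err <= abs_tol) {
      x <- small
      t <- t + h
      if (err < abs_tol / 32) h <- h * 2
      if (any(!is.finite(x)) || any(abs(x) > blowup_cap))
        return(list(x_end = x, diverged = TRUE, t_end = t))
    } else {
      h <- h / 2
      if (h < 1e-12)
        return(list(x_end = x, diverged = TRUE, t_end = t))
    }
  }
  list(x_end = x, diverged = FALSE, t_end = t)
}
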