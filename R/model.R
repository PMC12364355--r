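#' Right-hand side of the controlled myeloma model
#'
#' Evaluates the time derivatives of the three compartments
#' \deqn{dA/dt = \beta_A + \rho_A A (1 - A - P - N) - \mu_A A - \mu_{Au} u A}
#' \deqn{dP/dt = \rho_P P (1 - A - P - N) - \delta_P P + \delta_N N -
#'   \delta_{Pu} u P - \mu_P P - \mu_{Pu} u P - \alpha P / (\gamma + P + N)}
#' \deqn{dN/dt = \rho_N N (1 - A - P - N) + \delta_P P - \delta_N N +
#'   \delta_{Pu} u P - \mu_N N - \alpha N / (\gamma + P + N)}
#' All three share the space-competition factor `1 - A - P - N` and the
#' two cancer compartments share the saturating immune denominator
#' `gamma + P + N`.
#'
#' @param state numeric vector `c(A, P, N)` of population fractions.
#' @param u scalar control (drug dosage rate), `u >= 0`.
#' @param params an `mm_params` object.
#' @return Numeric vector `c(dA, dP, dN)`.
#' @export
model_rhs <- function(state, u, params) {
  state <- as.numeric(state)
  if (length(state) != 3 || any(!is.finite(state)))
    stop("state must be 3 finite numbers (A, P, N)", call. = FALSE)
  if (!is.finite(u) || u < 0)
    stop("control u must be finite and non-negative", call. = FALSE)
  out <- .rhs_cpp(params_to_vector(params), state, u)
  names(out) <- c("A", "P", "N")
  out
}

#' Jacobian of the model right-hand side
#'
#' @inheritParams model_rhs
#' @return 3x3 matrix, rows = equations (A, P, N), columns = states.
#' @keywords internal
#' @export
model_jacobian <- function(state, u, params) {
  .jacobian_cpp(params_to_vector(params), as.numeric(state), u)
}

#' Cancer-free (healthy) equilibrium
#'
#' With `P = N = 0` and no drug, the healthy compartment obeys
#' `dA/dt = beta_A + rho_A A (1 - A) - mu_A A`; its positive root
#' (quadratic formula) is the cancer-free steady state.
#'
#' @param params an `mm_params` object with `rho_A > 0`.
#' @return Named numeric `c(A, P, N)` with `P = N = 0`.
#' @export
healthy_equilibrium <- function(params) {
  p <- params
  if (p$rho_A <= 0) stop("rho_A must be positive", call. = FALSE)
  # rho_A A^2 + (mu_A - rho_A) A - beta_A = 0
  a <- p$rho_A
  b <- p$mu_A - p$rho_A
  cc <- -p$beta_A
  disc <- b * b - 4 * a * cc
  if (disc < 0)
    stop("no real healthy equilibrium for these parameters", call. = FALSE)
  A <- (-b + sqrt(disc)) / (2 * a)
  if (A < 0)
    stop("no non-negative healthy equilibrium for these parameters",
         call. = FALSE)
  st <- c(A = A, P = 0, N = 0)
  res <- max(abs(model_rhs(st, 0, params)))
  if (res > 1e-12)
    stop("healthy equilibrium residual too large: ", format(res),
         call. = FALSE)
  st
}

# damped Newton polish of a steady state of the uncontrolled system;
# degenerate components (identically zero row of the Jacobian with zero
# residual, e.g. N in the Null-N preset) are held fixed
.newton_polish <- function(state, u, params, tol = 1e-12, max_iter = 100) {
  x <- as.numeric(state)
  pv <- params_to_vector(params)
  for (i in seq_len(max_iter)) {
    f <- .rhs_cpp(pv, x, u)
    if (max(abs(f)) < tol) break
    J <- .jacobian_cpp(pv, x, u)
    act <- which(rowSums(abs(J)) > 1e-13 | abs(f) > tol)
    if (length(act) == 0) break
    step <- rep(0, 3)
    s <- tryCatch(solve(J[act, act, drop = FALSE], -f[act]),
                  error = function(e) NULL)
    if (is.null(s)) break
    step[act] <- s
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, 0)
      fn <- .rhs_cpp(pv, xn, u)
      if (max(abs(fn)) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- pmax(x + lam * step, 0)
  }
  x
}

#' Cancerous (persistent-disease) equilibrium
#'
#' The stable steady state with `P > 0` reached from the near-empty
#' marrow state `(A, P, N) = (0, 0.1, 0)` with no drug applied; this is
#' the standard initial condition for every optimal-control problem in
#' the package ("treatment starts at established disease"). Found by
#' long simulation followed by a damped Newton polish on the vector
#' field.
#'
#' @param params an `mm_params` object.
#' @param tol residual tolerance on the polished fixed point.
#' @param t_max simulation horizon cap before giving up.
#' @return Named numeric `c(A, P, N)` with `P > 0`.
#' @export
cancerous_equilibrium <- function(params, tol = 1e-12, t_max = 5000) {
  sim <- .steady_state_cpp(params_to_vector(params), c(0, 0.1, 0),
                           0, 1e-9, t_max, 0.01)
  if (!sim$converged)
    stop("no steady state reached within t_max; final residual ",
         format(sim$residual), call. = FALSE)
  x <- .newton_polish(sim$state, 0, params, tol = tol)
  res <- max(abs(.rhs_cpp(params_to_vector(params), x, 0)))
  if (res > 1e-10)
    stop("equilibrium polish failed; residual ", format(res), call. = FALSE)
  if (x[2] <= 0)
    stop("no persistent-cancer state found (P = 0 at convergence)",
         call. = FALSE)
  c(A = x[1], P = x[2], N = x[3])
}
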