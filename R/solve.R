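#' Forward-backward sweep solver configuration
#'
#' @param grid an `mm_grid` (default step 0.005 for control solves; use
#'   a refinement check at 0.001 for production numbers).
#' @param max_iterations iteration cap.
#' @param tol convergence tolerance on the relative L1 control change
#'   `||u_new - u_old||_1 / (||u_old||_1 + 1e-6)`; convergence is declared
#'   only after 3 consecutive iterations below `tol`.
#' @param omega initial relaxation weight of the control update
#'   `u <- (1 - omega) u + omega candidate`; adapted by a monotone line
#'   search (halved while the update would increase J, re-grown by 1.5x
#'   up to its initial value after an accepted step).
#' @param eps_sing singular-arc deadband on the switching function: where
#'   `|phi| < eps_sing` the candidate keeps the previous node value
#'   instead of snapping to a bound.
#' @param u_init initial control guess (scalar or per-node vector);
#'   default 0 everywhere.
#' @param u_cap upper cap on the control for strictly convex control
#'   costs (numerical safety; the quadratic problem is unbounded above).
#' @param stat_tol projected-stationarity stopping tolerance, used only
#'   for strictly convex control costs: iteration also stops when the
#'   pointwise KKT residual of `dH/du` falls below this for 3
#'   consecutive iterations.
#' @return An object of class `mm_solver_config`.
#' @export
solver_config <- function(grid, max_iterations = 20000, tol = 1e-6,
                          omega = 0.5, eps_sing = 1e-3, u_init = 0,
                          u_cap = 10, stat_tol = 1e-4) {
  stopifnot(inherits(grid, "mm_grid"), omega > 0, omega <= 1, tol > 0)
  structure(list(grid = grid, max_iterations = as.integer(max_iterations),
                 tol = tol, omega = omega, eps_sing = eps_sing,
                 u_init = u_init, u_cap = u_cap, stat_tol = stat_tol),
            class = "mm_solver_config")
}

#' Solve the optimal-control problem by forward-backward sweep
#'
#' Iterates: (i) integrate the state forward under the current control;
#' (ii) integrate the costate backward from `lambda(tf) = 0` along the
#' stored states; (iii) form the candidate control that minimises the
#' Hamiltonian pointwise (stationary rule for convex control costs, bang
#' rule with a singular deadband for control-affine costs); (iv) relax
#' `u <- (1 - omega) u + omega candidate`, accepting the step only if J
#' does not increase (monotone line search on omega). Stops when the
#' relative L1 control change stays below tolerance for 3 consecutive
#' iterations. A run forced to accept objective increases (at the omega
#' floor) for 20 consecutive iterations is aborted as divergent.
#'
#' @param params an `mm_params` object.
#' @param spec an `mm_cost_spec`.
#' @param config an `mm_solver_config`.
#' @param x0 initial state; default the persistent-cancer equilibrium
#'   of `params` (treatment starting at established disease).
#' @return An object of class `mm_solve_result`: fields `control`
#'   (`mm_control`), `trajectory` (`mm_trajectory`), `adjoint` matrix,
#'   `cost` (`mm_cost_breakdown`), `iterations`, `converged`, `diverged`,
#'   `cap_active`, `history` (per-iteration metric, J, omega) and
#'   `diagnostics` (see [pmp_diagnostics()]).
#' @export
solve_optimal_control <- function(params, spec, config, x0 = NULL) {
  stopifnot(inherits(params, "mm_params"), inherits(spec, "mm_cost_spec"),
            inherits(config, "mm_solver_config"))
  if (is.null(x0)) x0 <- cancerous_equilibrium(params)
  grid <- config$grid
  u0 <- config$u_init
  if (length(u0) == 1) u0 <- rep(u0, grid$n + 1)
  if (length(u0) != grid$n + 1)
    stop("u_init must be scalar or one value per grid node", call. = FALSE)

  w <- c(spec$w_u_lin, spec$w_u_quad, spec$w_c_lin, spec$w_c_quad)
  # deadband annealing (control-affine costs): converge first with a wide
  # singular deadband, which keeps the line search stable along long
  # near-singular arcs, then re-converge warm-started at the target
  # deadband so short bang arcs are resolved at full fidelity
  eps_stages <- if (spec$w_u_quad == 0 && config$eps_sing < 0.01)
    c(0.01, config$eps_sing) else config$eps_sing
  total_iter <- 0L
  hist <- list()
  raw <- NULL
  for (eps in eps_stages) {
    raw <- .fbsm_cpp(params_to_vector(params), as.numeric(x0), w, u0,
                     grid$dt, spec$u_max, config$u_cap,
                     config$max_iterations, config$tol, config$omega, eps,
                     config$stat_tol)
    if (raw$diverged)
      stop("forward-backward sweep diverged (J increased for 20 ",
           "consecutive iterations); see history", call. = FALSE)
    total_iter <- total_iter + raw$iterations
    hist[[length(hist) + 1]] <-
      data.frame(stage_eps = eps, metric = raw$metric_history,
                 J = raw$J_history, omega = raw$omega_history)
    u0 <- raw$u
  }
  raw$iterations <- total_iter
  history <- do.call(rbind, hist)

  upper <- if (spec$w_u_quad > 0) config$u_cap else spec$u_max
  control <- control_signal(raw$u, grid, lower = 0, upper = upper)
  X <- raw$states
  colnames(X) <- c("A", "P", "N")
  trajectory <- structure(list(grid = grid, states = X),
                          class = "mm_trajectory")
  L <- raw$adjoint
  colnames(L) <- c("lambda_A", "lambda_P", "lambda_N")

  res <- structure(list(
    control = control, trajectory = trajectory, adjoint = L,
    cost = evaluate_cost(trajectory, control, spec),
    iterations = raw$iterations, converged = raw$converged,
    diverged = raw$diverged, cap_active = raw$cap_active,
    history = history,
    params = params, spec = spec, config = config, x0 = x0),
    class = "mm_solve_result")
  res$diagnostics <- pmp_diagnostics(res)
  res
}

#' Pontryagin diagnostics for a solve result
#'
#' Per-node Hamiltonian, plus the form-specific optimality residual: the
#' stationarity residual `dH/du` at the returned control for convex
#' control costs, or the switching function `phi` together with the
#' fraction of nodes violating the bang rule (`sign(phi)` disagreeing
#' with the control while `|phi| > eps_sing`) for control-affine costs.
#'
#' @param result an `mm_solve_result`.
#' @return List with `H`, and either `stationarity` + `max_stationarity`
#'   or `phi` + `bang_violation_fraction`.
#' @export
pmp_diagnostics <- function(result) {
  stopifnot(inherits(result, "mm_solve_result"))
  params <- result$params
  spec <- result$spec
  X <- result$trajectory$states
  L <- result$adjoint
  u <- result$control$values
  C <- X[, 2] + X[, 3]
  f <- t(vapply(seq_len(nrow(X)), function(i)
    .rhs_cpp(params_to_vector(params), X[i, ], u[i]), numeric(3)))
  H <- spec$w_u_lin * u + spec$w_u_quad * u^2 + spec$w_c_lin * C +
    spec$w_c_quad * C^2 + rowSums(L * f)
  br <- L[, 1] * params$mu_Au * X[, 1] +
    L[, 2] * (params$mu_Pu + params$delta_Pu) * X[, 2] -
    L[, 3] * params$delta_Pu * X[, 2]
  out <- list(H = H)
  if (spec$w_u_quad > 0) {
    dHdu <- spec$w_u_lin + 2 * spec$w_u_quad * u - br
    # residual is meaningful where the bounds are inactive
    interior <- u > 1e-9 & u < result$control$upper - 1e-9
    out$stationarity <- dHdu
    out$max_stationarity <- if (any(interior)) max(abs(dHdu[interior])) else 0
  } else {
    phi <- spec$w_u_lin - br
    eps <- result$config$eps_sing
    want_max <- phi < -eps
    want_off <- phi > eps
    viol <- (want_max & u < spec$u_max - 1e-3) | (want_off & u > 1e-3)
    out$phi <- phi
    out$bang_violation_fraction <- mean(viol)
  }
  out
}

#' @export
print.mm_solve_result <- function(x, ...) {
  cat(sprintf("Optimal control solve (%s cost) on [%g, %g], dt = %g\n",
              x$spec$form, x$config$grid$t0, x$config$grid$tf,
              x$config$grid$dt))
  cat(sprintf("  iterations: %d, converged: %s\n", x$iterations,
              x$converged))
  cat(sprintf("  J = %.6g (control %.6g, cancer %.6g)\n", x$cost$total,
              x$cost$control_cost, x$cost$cancer_burden))
  if (!is.null(x$diagnostics$max_stationarity))
    cat(sprintf("  max interior |dH/du| = %.3g\n",
                x$diagnostics$max_stationarity))
  else
    cat(sprintf("  bang-rule violation fraction = %.3g\n",
                x$diagnostics$bang_violation_fraction))
  invisible(x)
}
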