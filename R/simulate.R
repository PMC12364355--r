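#' Uniform time grid
#'
#' @param tf end time; must exceed `t0`.
#' @param dt step size; `(tf - t0)/dt` must be an integer to within
#'   rounding tolerance.
#' @param t0 start time (default 0).
#' @return An object of class `mm_grid` with fields `t0`, `tf`, `dt`,
#'   `n` (steps) and `times` (the `n + 1` nodes).
#' @export
time_grid <- function(tf, dt = 0.001, t0 = 0) {
  stopifnot(is.finite(tf), is.finite(dt), is.finite(t0), tf > t0, dt > 0)
  n_real <- (tf - t0) / dt
  n <- round(n_real)
  if (abs(n_real - n) > 1e-8 * max(1, n))
    stop("(tf - t0) / dt must be an integer; got ", n_real, call. = FALSE)
  structure(list(t0 = t0, tf = tf, dt = dt, n = as.integer(n),
                 times = t0 + dt * seq(0, n)),
            class = "mm_grid")
}

#' Control signal on a time grid
#'
#' @param values numeric vector of control levels, one per grid node
#'   (recycled if scalar).
#' @param grid an `mm_grid`.
#' @param lower,upper admissible bounds; every value must lie inside.
#' @return An object of class `mm_control`.
#' @export
control_signal <- function(values, grid, lower = 0, upper = 1) {
  stopifnot(inherits(grid, "mm_grid"))
  if (length(values) == 1) values <- rep(values, grid$n + 1)
  if (length(values) != grid$n + 1)
    stop("control needs one value per grid node (", grid$n + 1, ")",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("control values must be finite", call. = FALSE)
  if (any(values < lower - 1e-12) || any(values > upper + 1e-12))
    stop("control values outside bounds [", lower, ", ", upper, "]",
         call. = FALSE)
  structure(list(grid = grid, values = pmin(pmax(values, lower), upper),
                 lower = lower, upper = upper),
            class = "mm_control")
}

#' Constant control
#' @param level scalar level.
#' @inheritParams control_signal
#' @return An `mm_control`.
#' @export
constant_control <- function(level, grid, lower = 0, upper = max(1, level)) {
  control_signal(rep(level, grid$n + 1), grid, lower, upper)
}

#' Integrate the controlled system with fixed-step RK4
#'
#' Classical fourth-order Runge-Kutta on the grid of `control`, with the
#' control linearly interpolated for the half-step stage evaluations.
#' Fixed stepping (no adaptivity) keeps the forward state pass and the
#' backward costate pass of the optimal-control solver on identical
#' grids.
#'
#' @param params an `mm_params` object.
#' @param x0 initial state `c(A, P, N)`, non-negative.
#' @param control an `mm_control` (or scalar, interpreted as constant).
#' @param grid grid to use when `control` is scalar.
#' @return An object of class `mm_trajectory`: list with `grid` and an
#'   `(n+1) x 3` `states` matrix with columns `A`, `P`, `N`.
#' @export
integrate_model <- function(params, x0, control, grid = NULL) {
  if (is.numeric(control) && length(control) == 1) {
    stopifnot(!is.null(grid))
    control <- constant_control(control, grid)
  }
  stopifnot(inherits(control, "mm_control"))
  x0 <- as.numeric(x0)
  if (length(x0) != 3 || any(!is.finite(x0)) || any(x0 < 0))
    stop("x0 must be 3 finite non-negative numbers", call. = FALSE)
  X <- .integrate_cpp(params_to_vector(params), x0, control$values,
                      control$grid$dt)
  colnames(X) <- c("A", "P", "N")
  structure(list(grid = control$grid, states = X), class = "mm_trajectory")
}

#' @export
as.data.frame.mm_trajectory <- function(x, ...) {
  data.frame(time = x$grid$times, A = x$states[, 1], P = x$states[, 2],
             N = x$states[, 3])
}

#' Simulate to steady state under constant control
#'
#' Integrates with constant control until the sup-norm of the vector
#' field falls below `tol` or `t_max` is reached. Non-convergence is
#' reported via the flag, not an error.
#'
#' @param params an `mm_params` object.
#' @param x0 initial state.
#' @param u constant control level.
#' @param tol residual tolerance (sup-norm of the rhs).
#' @param t_max horizon cap.
#' @param dt integration step.
#' @return List with `state`, `converged`, `residual`, `t`.
#' @export
find_steady_state <- function(params, x0, u = 0, tol = 1e-10,
                              t_max = 5000, dt = 0.001) {
  stopifnot(tol > 0)
  out <- .steady_state_cpp(params_to_vector(params), as.numeric(x0),
                           u, tol, t_max, dt)
  names(out$state) <- c("A", "P", "N")
  out
}
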