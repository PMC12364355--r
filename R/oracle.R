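#' Direct-transcription optimum on piecewise-constant controls
#'
#' Independent validation route for the sweep solver: parameterises the
#' control as piecewise constant on equal-length segments and minimises
#' the simulated objective with a general-purpose bounded quasi-Newton
#' optimiser (`stats::optim`, L-BFGS-B) from multiple random restarts.
#' Deliberately shares nothing with the Pontryagin machinery beyond the
#' simulator; it validates objective values only, not control structure.
#'
#' @param params an `mm_params` object.
#' @param x0 initial state.
#' @param spec an `mm_cost_spec`.
#' @param segments number of control segments (<= 40, desk-scale guard).
#' @param horizon end time (<= 50, desk-scale guard).
#' @param restarts optimiser restarts from random uniform starting
#'   controls (first start is always `u = 0`).
#' @param dt simulation step for objective evaluation.
#' @param upper per-segment upper bound; default the cost form's bound
#'   (1 for control-affine, 10 otherwise).
#' @param seed RNG seed for the restart draws.
#' @return List with `segment_values`, `J`, `restart_log` (one row per
#'   restart: start index, converged code, J).
#' @export
direct_transcription_optimum <- function(params, x0, spec, segments = 20,
                                         horizon = 20, restarts = 5,
                                         dt = 0.005, upper = NULL,
                                         seed = 0) {
  stopifnot(segments >= 1, segments <= 40, horizon <= 50)
  if (is.null(upper)) upper <- if (spec$w_u_quad > 0) 10 else spec$u_max
  grid <- time_grid(horizon, dt)
  pvec <- params_to_vector(params)
  x0 <- as.numeric(x0)
  seg_len <- horizon / segments
  # node i (time t) belongs to segment floor(t / seg_len), right-open
  seg_of_node <- pmin(floor(grid$times / seg_len), segments - 1) + 1

  objective <- function(seg) {
    u <- seg[seg_of_node]
    X <- .integrate_cpp(pvec, x0, u, dt)
    C <- X[, 2] + X[, 3]
    Lr <- spec$w_u_lin * u + spec$w_u_quad * u^2 + spec$w_c_lin * C +
      spec$w_c_quad * C^2
    .trap(Lr, dt)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  starts <- c(list(rep(0, segments)),
              replicate(max(restarts - 1, 0),
                        stats::runif(segments, 0, min(upper, 1)),
                        simplify = FALSE))
  best <- NULL
  log_rows <- list()
  for (k in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[k]], objective, method = "L-BFGS-B",
                   lower = rep(0, segments), upper = rep(upper, segments),
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) {
      log_rows[[k]] <- data.frame(restart = k, convergence = NA_integer_,
                                  J = NA_real_)
      next
    }
    log_rows[[k]] <- data.frame(restart = k, convergence = fit$convergence,
                                J = fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("direct transcription failed on every restart:\n",
         paste(utils::capture.output(do.call(rbind, log_rows)),
               collapse = "\n"), call. = FALSE)
  list(segment_values = best$par, J = best$value,
       restart_log = do.call(rbind, log_rows))
}

#' Finite-difference gradient of the objective in one control node
#'
#' Central difference of the simulated total cost with respect to a
#' single node value of the control, used to cross-check the
#' adjoint-based gradient `dJ/du_i = dH/du_i * dt` (trapezoid weight
#' `dt/2` at the end nodes).
#'
#' @param params an `mm_params` object.
#' @param x0 initial state.
#' @param control an `mm_control`.
#' @param spec an `mm_cost_spec`.
#' @param node node index (1-based).
#' @param eps perturbation size, in `[1e-6, 1e-2]`.
#' @return Scalar `dJ/du` at the node.
#' @export
finite_difference_gradient <- function(params, x0, control, spec, node,
                                       eps = 1e-4) {
  stopifnot(eps >= 1e-6, eps <= 1e-2,
            node >= 1, node <= control$grid$n + 1)
  pvec <- params_to_vector(params)
  x0 <- as.numeric(x0)
  dt <- control$grid$dt
  Jof <- function(u) {
    X <- .integrate_cpp(pvec, x0, u, dt)
    C <- X[, 2] + X[, 3]
    .trap(spec$w_u_lin * u + spec$w_u_quad * u^2 + spec$w_c_lin * C +
            spec$w_c_quad * C^2, dt)
  }
  up <- control$values; up[node] <- up[node] + eps
  dn <- control$values; dn[node] <- dn[node] - eps
  (Jof(up) - Jof(dn)) / (2 * eps)
}
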