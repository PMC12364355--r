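#' Cost-functional specification
#'
#' The objective is `J = integral of L(x, u) dt` over the horizon with no
#' terminal cost. The running cost is
#' `L = w_u_lin * u + w_u_quad * u^2 + w_c_lin * (P+N) + w_c_quad * (P+N)^2`.
#' The two canonical forms are `linear` (`L = u + P + N`, bounded control
#' `0 <= u <= 1`) and `quadratic` (`L = u^2 + (P+N)^2`, control bounded
#' below only; a numerical-safety cap is applied by the solver). `mixed`
#' takes explicit weights.
#'
#' @param form one of `"linear"`, `"quadratic"`, `"mixed"`.
#' @param w_u_lin,w_u_quad,w_c_lin,w_c_quad weights for the mixed form;
#'   ignored (and fixed) for the two canonical forms.
#' @param u_max upper control bound used when the cost is control-affine
#'   (default 1).
#' @return An object of class `mm_cost_spec`.
#' @export
cost_spec <- function(form = c("linear", "quadratic", "mixed"),
                      w_u_lin = 0, w_u_quad = 0, w_c_lin = 0, w_c_quad = 0,
                      u_max = 1) {
  form <- match.arg(form)
  w <- switch(form,
    linear = c(1, 0, 1, 0),
    quadratic = c(0, 1, 0, 1),
    mixed = c(w_u_lin, w_u_quad, w_c_lin, w_c_quad))
  if (any(!is.finite(w)) || any(w < 0))
    stop("cost weights must be finite and non-negative", call. = FALSE)
  structure(list(form = form, w_u_lin = w[1], w_u_quad = w[2],
                 w_c_lin = w[3], w_c_quad = w[4], u_max = u_max,
                 terminal = 0),
            class = "mm_cost_spec")
}

#' Running cost L(x, u)
#'
#' @param state numeric `c(A, P, N)`.
#' @param u control level(s); vectorised.
#' @param spec an `mm_cost_spec`.
#' @return Numeric running-cost value(s).
#' @export
running_cost <- function(state, u, spec) {
  stopifnot(inherits(spec, "mm_cost_spec"))
  C <- state[2] + state[3]
  spec$w_u_lin * u + spec$w_u_quad * u^2 + spec$w_c_lin * C +
    spec$w_c_quad * C^2
}

# trapezoid weights on a uniform grid restricted to [a, b] (node-aligned)
.trap <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - 0.5 * (y[1] + y[n]))
}

.window_idx <- function(grid, window) {
  i0 <- round((window[1] - grid$t0) / grid$dt) + 1
  i1 <- round((window[2] - grid$t0) / grid$dt) + 1
  if (i0 < 1 || i1 > grid$n + 1 || i1 < i0)
    stop("report window [", window[1], ", ", window[2],
         "] exceeds the trajectory grid", call. = FALSE)
  i0:i1
}

#' Total cost and its reporting decomposition
#'
#' Trapezoidal quadrature of the running cost over the trajectory grid.
#' The cancer burden is split between `P` and `N` in proportion to their
#' instantaneous contribution: at each node the cancer-cost integrand
#' (including the quadratic term `(P+N)^2`) is allocated by the ratio
#' `P : N`, so the shares sum exactly to the burden.
#'
#' @param trajectory an `mm_trajectory`.
#' @param control the paired `mm_control` (same grid).
#' @param spec an `mm_cost_spec`.
#' @param window reporting window `c(a, b)` for the headline totals;
#'   default the full horizon.
#' @param control_windows list of windows for partial control-cost
#'   integrals (defaults to `[0,5]` and `[0,20]`, clipped to the grid).
#' @param tol_bang tolerance for "control at its maximum" used for the
#'   initial maximal-run duration.
#' @return An object of class `mm_cost_breakdown`: fields `total`,
#'   `control_cost`, `cancer_burden`, `cancer_P`, `cancer_N`,
#'   `control_partial` (named by window), `initial_u_duration`, `window`.
#' @export
evaluate_cost <- function(trajectory, control, spec, window = NULL,
                          control_windows = list(c(0, 5), c(0, 20)),
                          tol_bang = 1e-3) {
  stopifnot(inherits(trajectory, "mm_trajectory"),
            inherits(control, "mm_control"), inherits(spec, "mm_cost_spec"))
  grid <- trajectory$grid
  if (!isTRUE(all.equal(grid$times, control$grid$times)))
    stop("trajectory and control must share a grid", call. = FALSE)
  if (is.null(window)) window <- c(grid$t0, grid$tf)
  idx <- .window_idx(grid, window)
  dt <- grid$dt

  P <- trajectory$states[idx, 2]
  N <- trajectory$states[idx, 3]
  u <- control$values[idx]
  C <- P + N

  u_cost <- spec$w_u_lin * u + spec$w_u_quad * u^2
  c_cost <- spec$w_c_lin * C + spec$w_c_quad * C^2
  fracP <- ifelse(C > 0, P / C, 0)
  fracN <- ifelse(C > 0, N / C, 0)

  control_cost <- .trap(u_cost, dt)
  cancer_burden <- .trap(c_cost, dt)
  cancer_P <- .trap(c_cost * fracP, dt)
  cancer_N <- .trap(c_cost * fracN, dt)

  partials <- vapply(control_windows, function(w) {
    w <- c(max(w[1], grid$t0), min(w[2], grid$tf))
    i <- .window_idx(grid, w)
    ui <- control$values[i]
    .trap(spec$w_u_lin * ui + spec$w_u_quad * ui^2, dt)
  }, numeric(1))
  names(partials) <- vapply(control_windows, function(w)
    paste0("[", w[1], ",", w[2], "]"), character(1))

  structure(list(total = control_cost + cancer_burden,
                 control_cost = control_cost,
                 cancer_burden = cancer_burden,
                 cancer_P = cancer_P, cancer_N = cancer_N,
                 control_partial = partials,
                 initial_u_duration = initial_max_duration(control, tol_bang),
                 window = window),
            class = "mm_cost_breakdown")
}

#' @export
print.mm_cost_breakdown <- function(x, ...) {
  cat(sprintf("Cost over [%g, %g]: J = %.6g (control %.6g + cancer %.6g)\n",
              x$window[1], x$window[2], x$total, x$control_cost,
              x$cancer_burden))
  cat(sprintf("  cancer burden split: P %.6g, N %.6g\n", x$cancer_P,
              x$cancer_N))
  cat(sprintf("  initial maximal-dose duration: %g\n", x$initial_u_duration))
  invisible(x)
}

#' Duration of the initial maximal-dose run
#'
#' The largest `T` such that every control node in `[t0, t0 + T]` is
#' within `tol_bang` of the upper bound. Returns 0 when the very first
#' node is below threshold; only the initial run counts.
#'
#' @param control an `mm_control`.
#' @param tol_bang "at maximum" tolerance.
#' @return Duration in time units.
#' @export
initial_max_duration <- function(control, tol_bang = 1e-3) {
  stopifnot(inherits(control, "mm_control"))
  at_max <- control$values >= control$upper - tol_bang
  if (!at_max[1]) return(0)
  k <- which(!at_max)
  last <- if (length(k) == 0) length(at_max) else k[1] - 1
  (last - 1) * control$grid$dt
}

#' Flatten a cost breakdown to one row
#' @param x an `mm_cost_breakdown`.
#' @return A one-row data frame.
#' @export
as.data.frame.mm_cost_breakdown <- function(x, ...) {
  row <- data.frame(total = x$total, control_cost = x$control_cost,
                    cancer_burden = x$cancer_burden, cancer_P = x$cancer_P,
                    cancer_N = x$cancer_N,
                    initial_u_duration = x$initial_u_duration)
  for (nm in names(x$control_partial))
    row[[paste0("control_", nm)]] <- x$control_partial[[nm]]
  row
}
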