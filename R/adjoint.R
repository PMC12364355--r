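#' Hamiltonian of the optimal-control problem
#'
#' `H(x, lambda, u) = L(x, u) + lambda . f(x, u)` where `f` is the model
#' vector field. Pontryagin's principle characterises the optimal control
#' as the pointwise minimiser of `H` over the admissible set.
#'
#' @param state numeric `c(A, P, N)`.
#' @param adjoint numeric costate `c(lambda_A, lambda_P, lambda_N)`.
#' @param u control level.
#' @param params an `mm_params` object.
#' @param spec an `mm_cost_spec`.
#' @return Scalar Hamiltonian value.
#' @export
hamiltonian <- function(state, adjoint, u, params, spec) {
  f <- model_rhs(state, u, params)
  running_cost(state, u, spec) + sum(as.numeric(adjoint) * f)
}

#' Costate dynamics lambda' = -dH/dx
#'
#' Analytic partial derivatives of the Hamiltonian with respect to
#' `(A, P, N)`, negated. Accounts for the shared competition factor
#' `1 - A - P - N` in all three equations and the immune denominator
#' `gamma + P + N` in the two cancer equations. Terminal condition is
#' `lambda(tf) = 0` (no terminal cost).
#'
#' @inheritParams hamiltonian
#' @return Numeric `c(dlambda_A, dlambda_P, dlambda_N)`.
#' @export
adjoint_rhs <- function(state, adjoint, u, params, spec) {
  out <- .adjoint_rhs_cpp(params_to_vector(params), as.numeric(state),
                          as.numeric(adjoint), u, spec$w_c_lin,
                          spec$w_c_quad)
  names(out) <- c("lambda_A", "lambda_P", "lambda_N")
  out
}

# d(lambda . f)/du = -(lambda_A mu_Au A + lambda_P (mu_Pu + delta_Pu) P
#                      - lambda_N delta_Pu P); shared by both rules below
.control_bracket <- function(state, adjoint, params) {
  adjoint[1] * params$mu_Au * state[1] +
    adjoint[2] * (params$mu_Pu + params$delta_Pu) * state[2] -
    adjoint[3] * params$delta_Pu * state[2]
}

#' Stationary control for a strictly convex (quadratic) control cost
#'
#' Solves `dH/du = 0` for the unique minimiser of the Hamiltonian:
#' `u* = clamp((bracket - w_u_lin) / (2 w_u_quad), 0, cap)` where the
#' bracket collects the control-linear part of `lambda . f`.
#'
#' @inheritParams hamiltonian
#' @param cap numerical-safety upper cap (default 10).
#' @return Scalar optimal control level.
#' @export
stationary_control_quadratic <- function(state, adjoint, params, spec,
                                         cap = 10) {
  if (spec$w_u_quad <= 0)
    stop("stationary control requires a quadratic control-cost term",
         call. = FALSE)
  br <- .control_bracket(as.numeric(state), as.numeric(adjoint), params)
  min(max((br - spec$w_u_lin) / (2 * spec$w_u_quad), 0), cap)
}

#' Switching function for a control-affine Hamiltonian
#'
#' `phi = dH/du = w_u_lin - bracket`. The candidate control is `u_max`
#' where `phi < 0` and `0` where `phi > 0`; an interval with `phi = 0`
#' is a singular arc.
#'
#' @inheritParams hamiltonian
#' @return Scalar `phi`.
#' @export
switching_function <- function(state, adjoint, params, spec) {
  if (spec$w_u_lin <= 0)
    stop("switching function requires a linear control-cost term",
         call. = FALSE)
  spec$w_u_lin - .control_bracket(as.numeric(state), as.numeric(adjoint),
                                  params)
}
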