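#' Model parameters for the myeloma-Daratumumab system
#'
#' Constructs the full set of rate constants for the three-compartment
#' model of healthy marrow cells (`A`), CD38+ myeloma (`P`) and CD38-
#' myeloma (`N`) under an anti-CD38 antibody control `u`. All populations
#' are fractions of the marrow carrying capacity and all rates are per
#' abstract time unit (the model is not calibrated to clock time).
#'
#' @param beta_A influx of healthy cells from the (implicit) stem-cell
#'   compartment.
#' @param rho_A,rho_P,rho_N proliferation rates of `A`, `P`, `N`.
#' @param mu_A,mu_P,mu_N death-or-exit rates of `A`, `P`, `N`.
#' @param mu_Au off-target mortality of `A` per unit of drug.
#' @param mu_Pu drug-induced mortality of `P` per unit of drug; fixed at 1
#'   in the default preset, which sets the scale of the control.
#' @param delta_P,delta_N expression-switching rates P to N and N to P.
#' @param delta_Pu drug-induced loss of CD38 expression (P to N) per unit
#'   of drug.
#' @param alpha immune control rate (maximum removal capacity scale).
#' @param gamma immune half-saturation constant, as a fraction of carrying
#'   capacity; must be strictly positive.
#'
#' @return An object of class `mm_params`: a named list of 14 rates.
#' @seealso [default_parameters()], [null_n_parameters()], [model_rhs()]
#' @export
model_parameters <- function(beta_A, rho_A, rho_P, rho_N, mu_A, mu_P, mu_N,
                             mu_Au, mu_Pu, delta_P, delta_N, delta_Pu,
                             alpha, gamma) {
  p <- list(beta_A = beta_A, rho_A = rho_A, rho_P = rho_P, rho_N = rho_N,
            mu_A = mu_A, mu_P = mu_P, mu_N = mu_N, mu_Au = mu_Au,
            mu_Pu = mu_Pu, delta_P = delta_P, delta_N = delta_N,
            delta_Pu = delta_Pu, alpha = alpha, gamma = gamma)
  vals <- unlist(p)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite numbers", call. = FALSE)
  if (any(vals < 0))
    stop("all parameters must be non-negative; got negative: ",
         paste(names(p)[vals < 0], collapse = ", "), call. = FALSE)
  if (gamma <= 0)
    stop("gamma must be strictly positive (immune denominator)", call. = FALSE)
  structure(p, class = "mm_params")
}

#' Default parameter preset (full model)
#'
#' The balanced full-model parameterisation: bistable cancer-free and
#' cancerous states under the saturating immune response, with
#' `delta_N = 10 * delta_P` and the control scale fixed by `mu_Pu = 1`.
#'
#' @return An `mm_params` object.
#' @export
default_parameters <- function() {
  model_parameters(
    beta_A = 0.1008, rho_A = 0.43, rho_P = 0.28, rho_N = 0.15,
    mu_A = 0.44, mu_P = 0.048, mu_N = 0.06,
    mu_Au = 0.1, mu_Pu = 1,
    delta_P = 0.003, delta_N = 0.03, delta_Pu = 0.2,
    alpha = 0.015, gamma = 0.1)
}

#' Null-N parameter preset (reduced negative-control model)
#'
#' Suppresses the CD38- compartment and the off-target effect: all `N`
#' rates and switching rates are zero and `mu_Au = 0`, with `rho_P` and
#' `mu_P` slightly readjusted. With `N(0) = 0` the `N` compartment stays
#' identically zero and the model reduces to a two-compartment
#' healthy-vs-cancer system used as a negative control.
#'
#' @return An `mm_params` object.
#' @export
null_n_parameters <- function() {
  model_parameters(
    beta_A = 0.1008, rho_A = 0.43, rho_P = 0.27, rho_N = 0,
    mu_A = 0.44, mu_P = 0.05, mu_N = 0,
    mu_Au = 0, mu_Pu = 1,
    delta_P = 0, delta_N = 0, delta_Pu = 0,
    alpha = 0.015, gamma = 0.1)
}

# fixed ordering used by the C++ kernels
.param_order <- c("beta_A", "rho_A", "rho_P", "rho_N", "mu_A", "mu_P", "mu_N",
                  "mu_Au", "mu_Pu", "delta_P", "delta_N", "delta_Pu",
                  "alpha", "gamma")

#' Flatten parameters to the numeric layout used internally
#' @param params an `mm_params` object.
#' @return Named numeric vector of length 14 in canonical order.
#' @keywords internal
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "mm_params"))
  unlist(params)[.param_order]
}

#' Apply named overrides to a parameter preset
#'
#' @param params an `mm_params` object.
#' @param ... named scalar overrides, e.g. `mu_Au = 0.5`. Unknown names
#'   are an error.
#' @return A new `mm_params` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "mm_params"))
  ov <- list(...)
  if (length(ov) == 0) return(params)
  bad <- setdiff(names(ov), .param_order)
  if (length(bad) > 0 || is.null(names(ov)) || any(names(ov) == ""))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p <- unclass(params)
  p[names(ov)] <- ov
  do.call(model_parameters, p)
}

#' @export
print.mm_params <- function(x, ...) {
  cat("Myeloma model parameters (per abstract time unit):\n")
  v <- params_to_vector(x)
  print(round(v, 6))
  invisible(x)
}
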