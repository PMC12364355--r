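#' Scenario specification for experiment drivers
#'
#' @param label short scenario name used in tables and error messages.
#' @param preset `"default"` or `"null_n"` base parameter set.
#' @param overrides named list of parameter overrides.
#' @param form cost form (`"linear"`, `"quadratic"`, `"mixed"`).
#' @param horizon solve horizon (time units).
#' @param dt solver step.
#' @param tol,max_iterations,omega,eps_sing solver settings (see
#'   [solver_config()]).
#' @param weights optional named list of mixed-form weights.
#' @return An object of class `mm_scenario`.
#' @export
scenario_spec <- function(label, preset = "default", overrides = list(),
                          form = "linear", horizon = 200, dt = 0.005,
                          tol = 1e-6, max_iterations = 20000, omega = 0.5,
                          eps_sing = 1e-3, weights = NULL) {
  stopifnot(preset %in% c("default", "null_n"))
  structure(list(label = label, preset = preset, overrides = overrides,
                 form = form, horizon = horizon, dt = dt, tol = tol,
                 max_iterations = as.integer(max_iterations), omega = omega,
                 eps_sing = eps_sing, weights = weights),
            class = "mm_scenario")
}

.scenario_params <- function(scenario) {
  base <- if (scenario$preset == "null_n") null_n_parameters()
          else default_parameters()
  do.call(update_parameters, c(list(base), scenario$overrides))
}

.scenario_spec_cost <- function(scenario) {
  if (scenario$form == "mixed") {
    w <- scenario$weights
    cost_spec("mixed", w_u_lin = w$w_u_lin, w_u_quad = w$w_u_quad,
              w_c_lin = w$w_c_lin, w_c_quad = w$w_c_quad)
  } else cost_spec(scenario$form)
}

#' Run one scenario end to end
#'
#' Equilibrium initial state, optimal-control solve, regime
#' classification, and a one-row cost table.
#'
#' @param scenario an `mm_scenario`.
#' @param x0 optional initial state override.
#' @return List with `result` (`mm_solve_result`), `form`
#'   (`mm_control_form`) and `row` (one-row data frame).
#' @export
run_scenario <- function(scenario, x0 = NULL) {
  stopifnot(inherits(scenario, "mm_scenario"))
  params <- .scenario_params(scenario)
  spec <- .scenario_spec_cost(scenario)
  grid <- time_grid(scenario$horizon, scenario$dt)
  cfg <- solver_config(grid, max_iterations = scenario$max_iterations,
                       tol = scenario$tol, omega = scenario$omega,
                       eps_sing = scenario$eps_sing)
  res <- tryCatch(
    solve_optimal_control(params, spec, cfg, x0 = x0),
    error = function(e)
      stop("scenario '", scenario$label, "': ", conditionMessage(e),
           call. = FALSE))
  form <- classify_control_form(res$control)
  row <- cbind(data.frame(label = scenario$label, form = scenario$form,
                          horizon = scenario$horizon,
                          regime = form$label,
                          converged = res$converged,
                          iterations = res$iterations),
               as.data.frame(res$cost))
  list(result = res, form = form, row = row)
}

#' Sweep one parameter over a set of values
#'
#' Runs [run_scenario()] once per value; individual failures are
#' recorded in the table (regime `"error"`) and the sweep continues.
#'
#' @param name parameter name to vary.
#' @param values numeric vector (>= 2 entries).
#' @param base an `mm_scenario` providing everything else.
#' @param keep_results keep the full solve results (memory-heavy).
#' @return Data frame, one row per value, plus a `results` attribute
#'   when `keep_results = TRUE`.
#' @export
sweep_parameter <- function(name, values, base, keep_results = FALSE) {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  rows <- list()
  results <- list()
  for (i in seq_along(values)) {
    ov <- base$overrides
    ov[[name]] <- values[i]
    sc <- base
    sc$overrides <- ov
    sc$label <- paste0(base$label, "_", name, "=", values[i])
    out <- tryCatch(run_scenario(sc), error = function(e) e)
    if (inherits(out, "error")) {
      rows[[i]] <- data.frame(label = sc$label, form = base$form,
                              horizon = sc$horizon, regime = "error",
                              converged = FALSE, iterations = NA_integer_,
                              total = NA_real_, control_cost = NA_real_,
                              cancer_burden = NA_real_, cancer_P = NA_real_,
                              cancer_N = NA_real_,
                              initial_u_duration = NA_real_)
      next
    }
    row <- out$row
    row[[name]] <- values[i]
    rows[[i]] <- row
    if (keep_results) results[[i]] <- out
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    # align columns across error and success rows
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  if (keep_results) attr(tab, "results") <- results
  tab
}

#' Grid of configurations probing the cyclic treatment regime
#'
#' Solves the linear-cost problem over the factorial grid of off-target
#' effect, expression-switching rates, drug-induced expression loss, and
#' immune strength used to map where cyclic (repeated pulsed) dosing is
#' optimal; runs with `alpha = 0.01` use the extended window `[0, 400]`
#' to avoid finite-window artefacts.
#'
#' @param mu_Au_values,switching,delta_Pu_values,alpha_values grid axes;
#'   `switching` is a list of `c(delta_P, delta_N)` pairs.
#' @param dt solver step.
#' @param max_iterations per-solve iteration cap.
#' @return Data frame with one labelled row per configuration.
#' @export
cyclic_regime_suite <- function(
    mu_Au_values = c(0, 0.1, 0.5),
    switching = list(c(0.003, 0.03), c(0.0003, 0.003), c(0, 0)),
    delta_Pu_values = c(0, 0.2, 2),
    alpha_values = c(0, 0.01, 0.015),
    dt = 0.005, max_iterations = 20000) {
  rows <- list()
  k <- 0
  for (mAu in mu_Au_values) for (sw in switching)
    for (dPu in delta_Pu_values) for (al in alpha_values) {
      k <- k + 1
      horizon <- if (al == 0.01) 400 else 200
      sc <- scenario_spec(
        label = sprintf("muAu=%g_dP=%g_dN=%g_dPu=%g_alpha=%g",
                        mAu, sw[1], sw[2], dPu, al),
        overrides = list(mu_Au = mAu, delta_P = sw[1], delta_N = sw[2],
                         delta_Pu = dPu, alpha = al),
        form = "linear", horizon = horizon, dt = dt,
        max_iterations = max_iterations)
      out <- tryCatch(run_scenario(sc), error = function(e) e)
      rows[[k]] <- if (inherits(out, "error"))
        data.frame(label = sc$label, mu_Au = mAu, delta_P = sw[1],
                   delta_N = sw[2], delta_Pu = dPu, alpha = al,
                   horizon = horizon, regime = "error",
                   total = NA_real_)
      else
        data.frame(label = sc$label, mu_Au = mAu, delta_P = sw[1],
                   delta_N = sw[2], delta_Pu = dPu, alpha = al,
                   horizon = horizon, regime = out$form$label,
                   total = out$row$total)
    }
  do.call(rbind, rows)
}

#' Finite-window artefact check by horizon extension
#'
#' Solves the same scenario at increasing horizons and compares the
#' controls over the common initial 50% of the shorter horizon. A
#' difference above `threshold` flags the solution as window-sensitive
#' (expected, and tolerated, for cyclic regimes, where the window length
#' biases the cycle timing).
#'
#' @param scenario an `mm_scenario`; its `horizon` field is ignored.
#' @param horizons numeric vector of at least 2 horizons.
#' @param threshold maximum tolerated control difference.
#' @return List with `max_diff` (consecutive-pair differences),
#'   `flagged`, `labels` (regime per horizon).
#' @export
horizon_extension_check <- function(scenario, horizons, threshold = 0.02) {
  stopifnot(length(horizons) >= 2)
  horizons <- sort(horizons)
  outs <- lapply(horizons, function(h) {
    sc <- scenario
    sc$horizon <- h
    run_scenario(sc)
  })
  diffs <- numeric(length(horizons) - 1)
  for (i in seq_len(length(horizons) - 1)) {
    n_cmp <- round(0.5 * horizons[i] / scenario$dt) + 1
    u1 <- outs[[i]]$result$control$values[seq_len(n_cmp)]
    u2 <- outs[[i + 1]]$result$control$values[seq_len(n_cmp)]
    # a bang edge displaced by a single node produces |du| ~ 1 however
    # well the solutions agree, so nodes within 1 time unit of a switch
    # in either control are excluded from the comparison
    mask_width <- round(1 / scenario$dt)
    edges <- which(abs(diff(u1)) > 0.1 | abs(diff(u2)) > 0.1)
    keep <- rep(TRUE, n_cmp)
    for (e in edges)
      keep[max(1, e - mask_width):min(n_cmp, e + mask_width)] <- FALSE
    diffs[i] <- if (any(keep)) max(abs(u1[keep] - u2[keep])) else 0
  }
  labels <- vapply(outs, function(o) o$form$label, character(1))
  flagged <- any(diffs > threshold) && !any(labels == "cyclic")
  list(max_diff = diffs, flagged = flagged, labels = labels,
       window_sensitive = any(diffs > threshold))
}
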