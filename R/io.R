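#' Write a trajectory (with paired control) as CSV
#'
#' Columns: time, A, P, N, u. Floating-point values are printed with 12
#' significant digits so regression diffs are meaningful.
#'
#' @param trajectory an `mm_trajectory`.
#' @param control the paired `mm_control` (same grid).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_trajectory_csv <- function(trajectory, control, path) {
  df <- as.data.frame(trajectory)
  df$u <- control$values
  .write_csv12(df, path)
}

#' Write a full solve result as CSV
#'
#' Columns: time, A, P, N, u, lambda_A, lambda_P, lambda_N, and the
#' form-specific optimality residual (`phi` for control-affine costs,
#' `dH_du` otherwise).
#'
#' @param result an `mm_solve_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_solve_csv <- function(result, path) {
  df <- as.data.frame(result$trajectory)
  df$u <- result$control$values
  df$lambda_A <- result$adjoint[, 1]
  df$lambda_P <- result$adjoint[, 2]
  df$lambda_N <- result$adjoint[, 3]
  if (!is.null(result$diagnostics$phi)) df$phi <- result$diagnostics$phi
  else df$dH_du <- result$diagnostics$stationarity
  .write_csv12(df, path)
}

.write_csv12 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise a solve result as a flat list (JSON-ready)
#'
#' @param result an `mm_solve_result`.
#' @param label optional scenario label.
#' @return Named list: form label, cost breakdown, iterations,
#'   convergence, regime classification.
#' @export
solve_summary <- function(result, label = NULL) {
  form <- classify_control_form(result$control)
  cb <- result$cost
  out <- list(label = label, cost_form = result$spec$form,
              regime = form$label,
              J = cb$total, control_cost = cb$control_cost,
              cancer_burden = cb$cancer_burden,
              cancer_P = cb$cancer_P, cancer_N = cb$cancer_N,
              control_partial = as.list(cb$control_partial),
              initial_u_duration = cb$initial_u_duration,
              iterations = result$iterations,
              converged = result$converged)
  if (!is.null(result$diagnostics$max_stationarity))
    out$max_stationarity <- result$diagnostics$max_stationarity
  else
    out$bang_violation_fraction <- result$diagnostics$bang_violation_fraction
  out
}

#' Write a summary (or any list) as JSON
#' @param x a list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration
#'
#' Configurations are JSON with keys `preset`, `parameters` (overrides),
#' `cost` (`form`, optional weights), `solver` (`horizon`, `dt`, `tol`,
#' `max_iterations`, `omega`, `eps_sing`), `output_dir`, `label`,
#' `oracle_seed`. Unknown top-level keys are rejected.
#'
#' @param path JSON config file.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("preset", "parameters", "cost", "solver", "output_dir",
             "label", "oracle_seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  defaults <- list(preset = "default", parameters = list(),
                   cost = list(form = "linear"),
                   solver = list(horizon = 200, dt = 0.005, tol = 1e-6,
                                 max_iterations = 20000, omega = 0.5,
                                 eps_sing = 1e-3),
                   output_dir = ".", label = "run", oracle_seed = 0)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]])) {
      miss <- setdiff(names(defaults[[k]]), names(cfg[[k]]))
      cfg[[k]][miss] <- defaults[[k]][miss]
    }
  }
  # parameters must round-trip against the preset
  base <- if (cfg$preset == "null_n") null_n_parameters()
          else default_parameters()
  cfg$params <- do.call(update_parameters,
                        c(list(base), as.list(cfg$parameters)))
  cfg
}

#' Write a run configuration
#' @param cfg list as returned by [read_run_config()] (the derived
#'   `params` entry is dropped).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg$params <- NULL
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.manifest <- function(cfg, elapsed, outputs) {
  list(config = cfg[setdiff(names(cfg), "params")],
       package_version = as.character(utils::packageVersion("daraopt")),
       r_version = R.version.string,
       wall_time_s = round(elapsed, 3),
       outputs = outputs)
}
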