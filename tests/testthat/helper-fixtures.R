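# shared fixtures; everything built in code, no stored data

fix_state <- c(0.3, 0.2, 0.01)

# independent term-by-term evaluation of the vector field, used as the
# arithmetic oracle for the C++ kernel (kept deliberately verbose)
oracle_rhs <- function(state, u, p) {
  A <- state[1]; P <- state[2]; N <- state[3]
  S <- 1 - A - P - N
  D <- p$gamma + P + N
  c(p$beta_A + p$rho_A * A * S - p$mu_A * A - p$mu_Au * u * A,
    p$rho_P * P * S - p$delta_P * P + p$delta_N * N - p$delta_Pu * u * P -
      p$mu_P * P - p$mu_Pu * u * P - p$alpha * P / D,
    p$rho_N * N * S + p$delta_P * P - p$delta_N * N + p$delta_Pu * u * P -
      p$mu_N * N - p$alpha * N / D)
}

# running cost by direct arithmetic
oracle_running_cost <- function(state, u, w) {
  C <- state[2] + state[3]
  w[1] * u + w[2] * u^2 + w[3] * C + w[4] * C^2
}

# small solved instances reused across solver tests (computed once)
quad_t20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- default_parameters()
      x0 <- cancerous_equilibrium(p)
      cfg <- solver_config(time_grid(20, 0.005), tol = 1e-8)
      cache <<- list(params = p, x0 = x0, spec = cost_spec("quadratic"),
                     result = solve_optimal_control(p, cost_spec("quadratic"),
                                                    cfg, x0 = x0))
    }
    cache
  }
})

# synthetic control signal from a piecewise specification
piecewise_control <- function(grid, pieces, upper = 1) {
  u <- numeric(grid$n + 1)
  for (p in pieces) u[grid$times >= p[1] & grid$times <= p[2]] <- p[3]
  control_signal(u, grid, upper = upper)
}
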