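test_that("quadratic solve satisfies the stationarity condition", {
  fx <- quad_t20()
  r <- fx$result
  expect_true(r$converged)
  expect_false(r$cap_active)
  expect_lt(r$diagnostics$max_stationarity, 1e-4)
  # control starts at its highest level and decreases overall
  u <- r$control$values
  expect_equal(max(u), u[1], tolerance = 1e-6)
  expect_gt(u[1], 0.3)
  expect_lt(u[length(u)], 0.05)
})

test_that("converged adjoint round-trips to its terminal condition", {
  fx <- quad_t20()
  r <- fx$result
  g <- r$control$grid
  # integrate lambda forward from lambda(t0) with plain RK4 and check
  # lambda(tf) = 0 (independent of the backward sweep implementation)
  lam <- r$adjoint[1, ]
  u <- r$control$values
  X <- r$trajectory$states
  h <- g$dt
  for (i in seq_len(g$n)) {
    x0i <- X[i, ]; x1i <- X[i + 1, ]; xm <- (x0i + x1i) / 2
    u0 <- u[i]; u1 <- u[i + 1]; um <- (u0 + u1) / 2
    k1 <- adjoint_rhs(x0i, lam, u0, fx$params, fx$spec)
    k2 <- adjoint_rhs(xm, lam + h / 2 * k1, um, fx$params, fx$spec)
    k3 <- adjoint_rhs(xm, lam + h / 2 * k2, um, fx$params, fx$spec)
    k4 <- adjoint_rhs(x1i, lam + h * k3, u1, fx$params, fx$spec)
    lam <- lam + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(max(abs(lam)), 1e-6)
})

test_that("adjoint gradient matches simulated finite differences", {
  fx <- quad_t20()
  r <- fx$result
  g <- r$control$grid
  set.seed(71)
  nodes <- sample(seq(50, g$n - 50), 5)
  for (nd in nodes) {
    fd <- finite_difference_gradient(fx$params, fx$x0, r$control, fx$spec,
                                     nd, eps = 1e-4)
    adj <- r$diagnostics$stationarity[nd] * g$dt
    # both should be ~0 at the optimum; compare on the gradient scale
    expect_lt(abs(fd - adj), 1e-4 * max(1, abs(fd)))
  }
})

test_that("solver beats trivial and constant-control baselines", {
  fx <- quad_t20()
  r <- fx$result
  g <- r$control$grid
  spec <- fx$spec
  for (u0 in seq(0, 1, by = 0.05)) {
    ctrl <- constant_control(u0, g, upper = 10)
    Jc <- evaluate_cost(integrate_model(fx$params, fx$x0, ctrl), ctrl,
                        spec)$total
    expect_lte(r$cost$total, Jc + 1e-9)
  }
})

test_that("solve result is internally consistent", {
  fx <- quad_t20()
  r <- fx$result
  # stored trajectory equals re-integration under the stored control
  traj <- integrate_model(fx$params, fx$x0, r$control)
  expect_lt(max(abs(traj$states - r$trajectory$states)), 1e-12)
  # stored cost equals evaluate_cost of the stored pair
  cb <- evaluate_cost(traj, r$control, fx$spec)
  expect_equal(r$cost$total, cb$total)
  # terminal costate is exactly zero by construction
  expect_equal(unname(r$adjoint[nrow(r$adjoint), ]), c(0, 0, 0))
})

test_that("warm starts are accepted and reach the same optimum", {
  fx <- quad_t20()
  g <- fx$result$control$grid
  cfg <- solver_config(g, tol = 1e-8, u_init = 0.8)
  r2 <- solve_optimal_control(fx$params, fx$spec, cfg, x0 = fx$x0)
  expect_true(r2$converged)
  expect_equal(r2$cost$total, fx$result$cost$total, tolerance = 1e-5)
})

test_that("linear solve on a short horizon is bang-consistent", {
  p <- null_n_parameters()
  x0 <- cancerous_equilibrium(p)
  cfg <- solver_config(time_grid(60, 0.005), tol = 1e-6)
  r <- solve_optimal_control(p, cost_spec("linear"), cfg, x0 = x0)
  expect_true(r$converged)
  expect_lt(r$diagnostics$bang_violation_fraction, 0.01)
  # switching function changes sign exactly once for the reduced model
  phi <- r$diagnostics$phi
  sgn <- sign(phi[abs(phi) > 1e-3])
  expect_equal(sum(diff(sgn) != 0), 1)
  # J beats both trivial policies
  g <- r$control$grid
  for (u0 in c(0, 1)) {
    ctrl <- constant_control(u0, g)
    Jc <- evaluate_cost(integrate_model(p, x0, ctrl), ctrl,
                        cost_spec("linear"))$total
    expect_lt(r$cost$total, Jc)
  }
})
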