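test_that("running cost reproduces both canonical forms", {
  lin <- cost_spec("linear")
  quad <- cost_spec("quadratic")
  expect_equal(running_cost(c(0, 0.2, 0.1), 0.5, lin), 0.8)
  expect_equal(running_cost(c(0, 0.2, 0.1), 0.5, quad), 0.34)
  # canonical forms pin their weights
  expect_equal(c(lin$w_u_lin, lin$w_u_quad, lin$w_c_lin, lin$w_c_quad),
               c(1, 0, 1, 0))
  expect_equal(c(quad$w_u_lin, quad$w_u_quad, quad$w_c_lin, quad$w_c_quad),
               c(0, 1, 0, 1))
  # degenerate mixed form
  zero <- cost_spec("mixed")
  expect_equal(running_cost(c(0.4, 0.3, 0.2), 1.7, zero), 0)
  # mixed agrees with direct arithmetic at random points
  set.seed(41)
  mx <- cost_spec("mixed", w_u_lin = 0.3, w_u_quad = 0.7, w_c_lin = 1.2,
                  w_c_quad = 0.4)
  for (k in 1:20) {
    st <- runif(3); u <- runif(1, 0, 2)
    expect_equal(running_cost(st, u, mx),
                 oracle_running_cost(st, u, c(0.3, 0.7, 1.2, 0.4)))
  }
})

test_that("evaluate_cost integrates and decomposes correctly", {
  g <- time_grid(10, 0.01)
  # constant states: P + N = 0.2, exact trapezoid values
  states <- cbind(A = rep(0.5, g$n + 1), P = rep(0.15, g$n + 1),
                  N = rep(0.05, g$n + 1))
  traj <- structure(list(grid = g, states = states), class = "mm_trajectory")
  ctrl <- constant_control(1, g)
  cb <- evaluate_cost(traj, ctrl, cost_spec("linear"))
  expect_equal(cb$total, 12)
  expect_equal(cb$control_cost, 10)
  expect_equal(cb$cancer_burden, 2)
  expect_equal(cb$cancer_P + cb$cancer_N, cb$cancer_burden)

  # quadratic split is proportional to the instantaneous P : N ratio
  g1 <- time_grid(1, 0.01)
  states1 <- cbind(A = rep(0, g1$n + 1), P = rep(0.2, g1$n + 1),
                   N = rep(0.1, g1$n + 1))
  traj1 <- structure(list(grid = g1, states = states1),
                     class = "mm_trajectory")
  cb1 <- evaluate_cost(traj1, constant_control(0, g1), cost_spec("quadratic"))
  expect_equal(cb1$cancer_burden, 0.09)
  expect_equal(cb1$cancer_P, 0.06)
  expect_equal(cb1$cancer_N, 0.03)

  # all-zero input gives a zero breakdown
  z <- structure(list(grid = g1, states = 0 * states1),
                 class = "mm_trajectory")
  cbz <- evaluate_cost(z, constant_control(0, g1), cost_spec("quadratic"))
  expect_equal(cbz$total, 0)
  expect_equal(cbz$cancer_P, 0)
})

test_that("cost is additive over adjacent windows", {
  p <- default_parameters()
  g <- time_grid(20, 0.01)
  ctrl <- control_signal(pmin(1, pmax(0, sin(g$times / 3) + 0.3)), g)
  traj <- integrate_model(p, c(0.2, 0.3, 0.05), ctrl)
  for (spec in list(cost_spec("linear"), cost_spec("quadratic"))) {
    whole <- evaluate_cost(traj, ctrl, spec, window = c(0, 20))
    a <- evaluate_cost(traj, ctrl, spec, window = c(0, 7))
    b <- evaluate_cost(traj, ctrl, spec, window = c(7, 20))
    expect_equal(a$total + b$total, whole$total, tolerance = 1e-12)
    expect_equal(a$cancer_P + b$cancer_P, whole$cancer_P, tolerance = 1e-12)
  }
  expect_error(evaluate_cost(traj, ctrl, cost_spec("linear"),
                             window = c(0, 30)), "exceeds")
})

test_that("linear cost is monotone in the control", {
  p <- default_parameters()
  g <- time_grid(10, 0.01)
  traj <- integrate_model(p, c(0.2, 0.3, 0.05), constant_control(0, g))
  spec <- cost_spec("linear")
  set.seed(51)
  u1 <- runif(g$n + 1, 0, 0.5)
  u2 <- u1 + runif(g$n + 1, 0, 0.5)  # pointwise >= u1
  J1 <- evaluate_cost(traj, control_signal(u1, g), spec)$total
  J2 <- evaluate_cost(traj, control_signal(u2, g), spec)$total
  expect_gte(J2, J1)
})

test_that("initial_max_duration picks out the first maximal run", {
  g <- time_grid(6, 0.01)
  expect_equal(initial_max_duration(
    piecewise_control(g, list(c(0, 3, 1)))), 3)
  expect_equal(initial_max_duration(constant_control(0, g)), 0)
  expect_equal(initial_max_duration(
    piecewise_control(g, list(c(0, 2, 1), c(2.01, 4, 0.5), c(4.01, 6, 1)))),
    2)
})
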