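test_that("rhs matches hand-computed fixtures exactly", {
  p <- default_parameters()
  # empty marrow: only the stem-cell influx acts
  expect_equal(unname(model_rhs(c(0, 0, 0), 0, p)), c(0.1008, 0, 0))
  # term-by-term frozen values (direct arithmetic with the table rates)
  expect_lt(max(abs(model_rhs(fix_state, 0, p) -
                    c(0.03201, 0.00786258064516129,
                      -0.0000488709677419355))), 1e-15)
  expect_lt(max(abs(model_rhs(fix_state, 1, p) -
                    c(0.00201, -0.232137419354839,
                      0.0399511290322581))), 1e-15)
})

test_that("rhs agrees with the independent arithmetic oracle", {
  set.seed(11)
  for (p in list(default_parameters(), null_n_parameters())) {
    for (k in 1:25) {
      st <- runif(3, 0, 0.6)
      u <- runif(1, 0, 1.5)
      expect_equal(unname(model_rhs(st, u, p)), oracle_rhs(st, u, p),
                   tolerance = 1e-14)
    }
  }
})

test_that("rhs rejects non-finite input and is safe at P = N = 0", {
  p <- default_parameters()
  expect_error(model_rhs(c(NA, 0, 0), 0, p), "finite")
  expect_error(model_rhs(c(0.1, 0.1, 0.1), -0.5, p), "non-negative")
  # immune denominator is gamma > 0, no singularity at the origin
  expect_true(all(is.finite(model_rhs(c(0.5, 0, 0), 1, p))))
})

test_that("Null-N preset keeps the N compartment identically zero", {
  q <- null_n_parameters()
  set.seed(21)
  for (k in 1:20) {
    st <- c(runif(2, 0, 0.8), 0)
    u <- runif(1, 0, 2)
    expect_identical(unname(model_rhs(st, u, q))[3], 0)
  }
})

test_that("non-negative octant is forward-invariant on its boundary", {
  set.seed(31)
  p <- default_parameters()
  for (k in 1:100) {
    st <- runif(3, 0, 0.5)
    u <- runif(1, 0, 1)
    face <- sample(1:3, 1)
    st[face] <- 0
    f <- model_rhs(st, u, p)
    expect_gte(f[face], 0)
    # boundary derivative identities
    if (face == 1) expect_equal(unname(f[1]), p$beta_A)
    if (face == 2) expect_equal(unname(f[2]), p$delta_N * st[3])
    if (face == 3)
      expect_equal(unname(f[3]), (p$delta_P + p$delta_Pu * u) * st[2])
  }
})

test_that("healthy equilibrium is the quadratic-formula root", {
  p <- default_parameters()
  he <- healthy_equilibrium(p)
  # independent oracle: positive root of rho_A A^2 + (mu_A - rho_A) A - beta_A
  root <- (-(0.44 - 0.43) + sqrt((0.44 - 0.43)^2 + 4 * 0.43 * 0.1008)) /
    (2 * 0.43)
  expect_equal(unname(he[1]), root, tolerance = 1e-12)
  expect_equal(unname(he[1]), 0.47268, tolerance = 1e-4)
  expect_equal(unname(he[2:3]), c(0, 0))
  expect_lt(max(abs(model_rhs(he, 0, p))), 1e-12)
  # Eq for A has identical rates in both presets
  expect_equal(healthy_equilibrium(null_n_parameters()), he)
  # zero influx with balanced growth: A* = 0
  p0 <- update_parameters(p, beta_A = 0, mu_A = p$rho_A)
  expect_equal(unname(healthy_equilibrium(p0)[1]), 0)
})

test_that("cancerous equilibrium is a genuine fixed point with N << P", {
  p <- default_parameters()
  ce <- cancerous_equilibrium(p)
  expect_gt(ce["P"], 0)
  expect_gt(ce["N"], 0)
  expect_lt(ce["N"] / ce["P"], 0.2)  # CD38- marginal without drug
  expect_lt(max(abs(model_rhs(ce, 0, p))), 1e-10)

  cn <- cancerous_equilibrium(null_n_parameters())
  expect_identical(unname(cn["N"]), 0)
  expect_lt(max(abs(model_rhs(cn, 0, null_n_parameters()))), 1e-10)
})

test_that("Null-N dynamics reduce to a two-compartment system", {
  # bit-comparable against a hand-written (A, P) model over a long run
  q <- null_n_parameters()
  grid <- time_grid(10, 0.001)
  traj <- integrate_model(q, c(0, 0.1, 0), constant_control(0.3, grid))
  rhs2 <- function(x, u) {
    S <- 1 - x[1] - x[2]
    c(q$beta_A + q$rho_A * x[1] * S - q$mu_A * x[1],
      q$rho_P * x[2] * S - q$mu_P * x[2] - q$mu_Pu * u * x[2] -
        q$alpha * x[2] / (q$gamma + x[2]))
  }
  x <- c(0, 0.1)
  for (i in seq_len(grid$n)) {
    h <- grid$dt
    k1 <- rhs2(x, 0.3); k2 <- rhs2(x + h / 2 * k1, 0.3)
    k3 <- rhs2(x + h / 2 * k2, 0.3); k4 <- rhs2(x + h * k3, 0.3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(unname(traj$states[grid$n + 1, 1:2]), x, tolerance = 1e-13)
  expect_identical(max(abs(traj$states[, 3])), 0)
})
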