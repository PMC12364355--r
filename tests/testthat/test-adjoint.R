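test_that("Hamiltonian assembles cost and dynamics", {
  p <- default_parameters()
  lin <- cost_spec("linear")
  # zero costate: H reduces to the running cost
  set.seed(61)
  for (k in 1:10) {
    st <- runif(3, 0, 0.5); u <- runif(1)
    expect_equal(hamiltonian(st, c(0, 0, 0), u, p, lin),
                 running_cost(st, u, lin))
  }
  # empty marrow, lambda_A = 2: H = 2 * beta_A
  expect_equal(hamiltonian(c(0, 0, 0), c(2, 0, 0), 0, p, lin), 0.2016)
})

test_that("dH/du matches central finite differences", {
  p <- default_parameters()
  set.seed(62)
  for (spec in list(cost_spec("linear"), cost_spec("quadratic"))) {
    for (k in 1:50) {
      st <- runif(3, 0, 0.6); lam <- rnorm(3); u <- runif(1, 0.1, 0.9)
      h <- 1e-6
      fd <- (hamiltonian(st, lam, u + h, p, spec) -
             hamiltonian(st, lam, u - h, p, spec)) / (2 * h)
      analytic <- if (spec$w_u_quad > 0) {
        2 * u - (lam[1] * p$mu_Au * st[1] +
                 lam[2] * (p$mu_Pu + p$delta_Pu) * st[2] -
                 lam[3] * p$delta_Pu * st[2])
      } else switching_function(st, lam, p, spec)
      expect_equal(fd, analytic, tolerance = 1e-8)
    }
  }
})

test_that("adjoint_rhs equals -dH/dx by central finite differences", {
  set.seed(63)
  for (parms in list(default_parameters(), null_n_parameters())) {
    for (spec in list(cost_spec("linear"), cost_spec("quadratic"))) {
      for (k in 1:50) {
        st <- runif(3, 0.05, 0.6); lam <- rnorm(3); u <- runif(1, 0, 1)
        got <- adjoint_rhs(st, lam, u, parms, spec)
        h <- 1e-6
        fd <- vapply(1:3, function(j) {
          up <- st; up[j] <- up[j] + h
          dn <- st; dn[j] <- dn[j] - h
          -(hamiltonian(up, lam, u, parms, spec) -
            hamiltonian(dn, lam, u, parms, spec)) / (2 * h)
        }, numeric(1))
        expect_lt(max(abs(got - fd)), 1e-7)
      }
    }
  }
})

test_that("zero costate isolates the state-cost gradient", {
  p <- default_parameters()
  got <- adjoint_rhs(c(0.3, 0.2, 0.1), c(0, 0, 0), 0.4, p,
                     cost_spec("linear"))
  expect_equal(unname(got), c(0, -1, -1))
})

test_that("stationary control solves the pointwise minimisation", {
  p <- default_parameters()
  quad <- cost_spec("quadratic")
  # frozen arithmetic example
  expect_equal(
    stationary_control_quadratic(fix_state, c(0.1, 2, 1), p, quad),
    0.2215)
  expect_equal(
    stationary_control_quadratic(fix_state, c(0, 0, 0), p, quad), 0)
  # costate pushing the bracket negative clips at zero
  expect_equal(
    stationary_control_quadratic(fix_state, c(-1, -2, 5), p, quad), 0)
  # numerical 1-D minimisation oracle at random points
  set.seed(64)
  for (k in 1:20) {
    st <- runif(3, 0, 0.6); lam <- rnorm(3, sd = 2)
    ustar <- stationary_control_quadratic(st, lam, p, quad)
    opt <- stats::optimize(function(u) hamiltonian(st, lam, u, p, quad),
                           c(0, 10))
    expect_equal(ustar, min(max(opt$minimum, 0), 10), tolerance = 1e-4)
  }
})

test_that("switching function sign gives the bang candidate", {
  p <- default_parameters()
  lin <- cost_spec("linear")
  expect_equal(switching_function(fix_state, c(0.1, 2, 1), p, lin), 0.557)
  expect_equal(switching_function(fix_state, c(0, 0, 0), p, lin), 1)
  expect_error(switching_function(fix_state, c(0, 0, 0), p,
                                  cost_spec("quadratic")), "linear")
})
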