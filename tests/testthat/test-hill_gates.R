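reg1 <- function(u, K = 1, n = 4) list(list(level = u, hill = hill_input(K, n)))
reg2 <- function(u1, u2, K1 = 1, n1 = 4, K2 = 1, n2 = 4) {
  list(list(level = u1, hill = hill_input(K1, n1)),
       list(level = u2, hill = hill_input(K2, n2)))
}

test_that("promoter activities hit their landmark values", {
  expect_equal(promoter_activity("NOT", reg1(0)), 1.0)
  expect_equal(promoter_activity("NOT", reg1(2, K = 2, n = 3.7)), 0.5)
  expect_equal(promoter_activity("BUFFER", reg1(0)), 0.0)
  expect_equal(promoter_activity("AND", reg2(1, 2, K1 = 1, K2 = 2)), 0.25)
  expect_equal(promoter_activity("NAND", reg2(1, 2, K1 = 1, K2 = 2)), 0.75)
  expect_equal(promoter_activity("XOR", reg2(1, 0, K1 = 1)), 0.5)
  expect_equal(promoter_activity("NOR", reg2(0, 0)), 1.0)
  expect_equal(promoter_activity("OR", reg2(0, 0)), 0.0)
})

test_that("activity preconditions raise classed errors", {
  expect_error(promoter_activity("NOT", reg2(1, 1)), class = "geneclock_arity_error")
  expect_error(promoter_activity("AND", reg1(1)), class = "geneclock_arity_error")
  expect_error(promoter_activity("NOT", reg1(-0.1)), class = "geneclock_domain_error")
  expect_error(hill_input(0, 4), class = "geneclock_domain_error")
  expect_error(hill_input(1, -1), class = "geneclock_domain_error")
  expect_error(gate_kinetics(1, 0), class = "geneclock_domain_error")
  expect_error(txtl_kinetics(1, 0, 1, 1), class = "geneclock_domain_error")
})

test_that("complementarity identities hold to 1e-12 on random inputs", {
  set.seed(42)
  for (i in seq_len(1000)) {
    u1 <- stats::runif(1, 0, 5); u2 <- stats::runif(1, 0, 5)
    K1 <- stats::runif(1, 0.2, 3); K2 <- stats::runif(1, 0.2, 3)
    n1 <- stats::runif(1, 0.5, 6); n2 <- stats::runif(1, 0.5, 6)
    r1 <- reg1(u1, K1, n1)
    r2 <- reg2(u1, u2, K1, n1, K2, n2)
    expect_lt(abs(promoter_activity("NOT", r1) + promoter_activity("BUFFER", r1) - 1),
              1e-12)
    expect_lt(abs(promoter_activity("NAND", r2) - (1 - promoter_activity("AND", r2))),
              1e-12)
    expect_lt(abs(promoter_activity("NOR", r2) - (1 - promoter_activity("OR", r2))),
              1e-12)
    expect_lt(abs(promoter_activity("XOR", r2) -
                  (promoter_activity("OR", r2) - promoter_activity("AND", r2))),
              1e-12)
  }
})

test_that("activities are bounded and monotone in their inputs", {
  set.seed(7)
  us <- seq(0, 4, length.out = 40)
  for (kind in c("AND", "OR")) {
    for (u2 in c(0.3, 1, 2.5)) {
      f <- vapply(us, function(u) promoter_activity(kind, reg2(u, u2)), numeric(1))
      expect_true(all(f >= 0 & f <= 1))
      expect_true(all(diff(f) >= -1e-14))
    }
  }
  for (kind in c("NAND", "NOR")) {
    for (u2 in c(0.3, 1, 2.5)) {
      f <- vapply(us, function(u) promoter_activity(kind, reg2(u, u2)), numeric(1))
      expect_true(all(f >= 0 & f <= 1))
      expect_true(all(diff(f) <= 1e-14))
    }
  }
})

test_that("kinetics reduction matches the lumped-rate formulas", {
  k <- reduce_kinetics(txtl_kinetics(alpha = 1, lambda = 4, beta = 2, gamma = 0.7))
  expect_equal(k$rho, 0.5)
  expect_equal(k$rho0, 0)
  expect_equal(k$gamma, 0.7)
  expect_equal(reduce_kinetics(txtl_kinetics(0, 1, 5, 1))$rho, 0)
  # inverse mapping: alpha = rho * lambda / beta recovers rho
  for (pars in list(c(2, 3), c(0.5, 1.7))) {
    beta <- pars[1]; lambda <- pars[2]
    k2 <- reduce_kinetics(txtl_kinetics(0.6851 * lambda / beta, lambda, beta, 1))
    expect_equal(k2$rho, 0.6851)
  }
})

test_that("full and reduced models share their steady state", {
  kin <- txtl_kinetics(alpha = 1.3, lambda = 2.5, beta = 0.8, gamma = 0.4,
                       alpha0 = 0.1)
  red <- reduce_kinetics(kin)
  regs <- reg1(0.7, K = 0.5, n = 4)
  f <- promoter_activity("BUFFER", regs)
  # analytic steady state of the full model
  m_ss <- (kin$alpha * f + kin$alpha0) / kin$lambda
  p_ss <- kin$beta * m_ss / kin$gamma
  expect_equal(unname(full_gate_rhs(kin, "BUFFER", regs, m_ss, p_ss)), c(0, 0))
  # the reduced model is stationary at the same protein level
  expect_equal(reduced_gate_rhs(red, "BUFFER", regs, p_ss), 0)
  expect_equal(p_ss, (red$rho * f + red$rho0) / red$gamma)
})

test_that("reduced rate law landmarks", {
  regs <- reg1(10, K = 1e-6, n = 4)  # activity ~ 1
  expect_equal(reduced_gate_rhs(gate_kinetics(1, 1), "BUFFER", regs, 0), 1,
               tolerance = 1e-8)
  regs2 <- reg1(0.5, K = 0.5, n = 4)
  expect_equal(reduced_gate_rhs(gate_kinetics(1, 1), "BUFFER", regs2, 0.5), 0)
  kin <- gate_kinetics(1.7, 0.6, 0.2)
  f <- promoter_activity("NOT", regs2)
  expect_equal(reduced_gate_rhs(kin, "NOT", regs2, (kin$rho * f + kin$rho0) / kin$gamma), 0)
})

test_that("buffer steady state is sigmoidal with half-max at u = K", {
  kin <- gate_kinetics(1, 1, 0)
  h <- hill_input(0.8, 4)
  expect_equal(buffer_steady_state(kin, h, 0.8), 0.5)
  expect_equal(buffer_steady_state(kin, h, 0), 0)
  expect_equal(buffer_steady_state(kin, h, 1e9), 1, tolerance = 1e-8)
  kin2 <- gate_kinetics(2, 0.5, 0.1)
  expect_equal(buffer_steady_state(kin2, h, 0), 0.2)
  lo <- buffer_steady_state(kin2, h, 0)
  hi <- (kin2$rho + kin2$rho0) / kin2$gamma
  expect_equal(buffer_steady_state(kin2, h, h$K), (lo + hi) / 2)
  u <- seq(0, 5, length.out = 60)
  expect_true(all(diff(buffer_steady_state(kin2, h, u)) > 0))
})

test_that("buffer gain equals the slope of the steady-state curve at u = K", {
  expect_equal(buffer_gain(gate_kinetics(1, 1), hill_input(0.5, 4)), 2.0)
  expect_equal(buffer_gain(gate_kinetics(1, 1), hill_input(1.76, 4)),
               4 / (4 * 1.76))
  for (pars in list(list(kin = gate_kinetics(1, 1), h = hill_input(0.5, 4)),
                    list(kin = gate_kinetics(1, 1), h = hill_input(1.76, 4)),
                    list(kin = gate_kinetics(2.3, 0.7, 0.4), h = hill_input(1.2, 2.5)))) {
    kin <- pars$kin; h <- pars$h
    eps <- 1e-6 * h$K
    slope <- (buffer_steady_state(kin, h, h$K + eps) -
              buffer_steady_state(kin, h, h$K - eps)) / (2 * eps)
    expect_equal(buffer_gain(kin, h), slope, tolerance = 1e-6)
  }
})
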