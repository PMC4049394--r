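single_buffer <- function(level = 0.5, K = 0.5, rho = 1, gamma = 1, rho0 = 0) {
  circuit_spec(
    species = data.frame(name = "p", initial = 0),
    gates = list(gate_node("p", "BUFFER", gate_kinetics(rho, gamma, rho0),
                           list(regulator("u", K, 4)))),
    sources = c(u = level))
}

test_that("repressilator builder reproduces the printed defaults", {
  osc <- build_repressilator(chi = 0.5)
  expect_equal(osc$species$name, c("p_lacI", "p_tetR", "p_cI"))
  expect_equal(osc$species$initial, c(0.7, 1.2, 1.7))
  expect_length(validate_circuit(osc), 0)
  kinds <- vapply(osc$gates, `[[`, character(1), "kind")
  expect_equal(unique(kinds), "NOT")
  # ring wiring: lacI <- cI <- tetR <- lacI
  srcs <- vapply(osc$gates, function(g) g$regulators[[1]]$source, character(1))
  expect_equal(srcs, c("p_cI", "p_lacI", "p_tetR"))
  # K = 1 reproduces plain p^4 denominators
  expect_equal(vapply(osc$gates, function(g) g$regulators[[1]]$hill$K, numeric(1)),
               rep(1, 3))
  expect_error(build_repressilator(chi = 0), class = "geneclock_domain_error")
})

test_that("compiled vector field matches hand-computed derivatives", {
  circ <- single_buffer(level = 0.5)
  rhs <- compile_rhs(circ)
  expect_equal(unname(rhs$fun(0, c(p = 0), NULL)[[1]]), 0.5)  # f = 1/2 at u = K
  # any state decays toward its own steady state
  expect_equal(unname(rhs$fun(0, c(p = 0.5), NULL)[[1]]), 0)
  osc <- build_repressilator(chi = 0.5)
  r2 <- compile_rhs(osc)
  y <- c(0.7, 1.2, 1.7)
  d <- unname(r2$fun(0, y, NULL)[[1]])
  chi <- 0.5
  expect_equal(d[1], chi * (0.6851 / (1 + y[3]^4) - 0.233 * y[1]))
  expect_equal(d[3], chi * (0.6851 / (1 + y[2]^4) - 0.233 * y[3]))
  expect_true(all(is.finite(d)))
})

test_that("wiring problems are reported as diagnostics and compile errors", {
  bad <- circuit_spec(
    species = data.frame(name = "p", initial = 0),
    gates = list(gate_node("p", "BUFFER", gate_kinetics(1, 1),
                           list(regulator("ghost", 0.5, 4)))))
  expect_match(validate_circuit(bad), "unknown signal ghost")
  expect_error(compile_rhs(bad), class = "geneclock_wiring_error")
  # duplicate producer
  dup <- circuit_spec(
    species = data.frame(name = "p", initial = 0),
    gates = list(
      gate_node("p", "BUFFER", gate_kinetics(1, 1), list(regulator("u", 0.5, 4))),
      gate_node("p", "NOT", gate_kinetics(1, 1), list(regulator("u", 0.5, 4)))),
    sources = c(u = 1))
  expect_match(paste(validate_circuit(dup), collapse = "; "), "duplicate producer")
  # arity mismatch is impossible through gate_node(); check the constructor
  expect_error(gate_node("p", "NOT", gate_kinetics(1, 1),
                         list(regulator("a", 1, 4), regulator("b", 1, 4))),
               class = "geneclock_arity_error")
  # unbound free input
  ff <- build_jk_rising(j_src = 1, k_src = 1, clk_src = "clk")
  expect_error(compile_rhs(ff), class = "geneclock_wiring_error")
})

test_that("cascade merges, binds inputs, and rejects collisions", {
  osc <- build_repressilator(chi = 0.5)
  shaped <- build_pwm_circuit(osc, "p_cI", shaper_reference_design("pulse10"))
  expect_equal(nrow(shaped$species), 9L)
  expect_length(validate_circuit(shaped), 0)
  # empty downstream is the identity
  empty <- circuit_spec(species = data.frame(name = character(), initial = numeric()),
                        gates = list())
  merged <- cascade(osc, empty)
  expect_equal(merged$species, osc$species)
  expect_length(merged$gates, 3L)
  # collision
  expect_error(cascade(osc, osc), class = "geneclock_naming_error")
  # wiring to a nonexistent upstream target
  down <- circuit_spec(species = data.frame(name = "q", initial = 0),
                       gates = list(gate_node("q", "BUFFER", gate_kinetics(1, 1),
                                              list(regulator("in1", 0.5, 4)))),
                       inputs = "in1")
  expect_error(cascade(osc, down, c(in1 = "nope")), class = "geneclock_wiring_error")
  expect_error(cascade(osc, down, c(oops = "p_cI")), class = "geneclock_wiring_error")
  ok <- cascade(osc, down, c(in1 = "p_cI"))
  expect_length(validate_circuit(ok), 0)
  expect_length(ok$inputs, 0)
})

test_that("feed-forward composition preserves upstream dynamics", {
  set.seed(11)
  osc <- build_repressilator(chi = 0.5)
  shaped <- build_pwm_circuit(osc, "p_cI", shaper_reference_design("dc"))
  f_a <- compile_rhs(osc)$fun
  f_ab <- compile_rhs(shaped)$fun
  for (i in 1:20) {
    ya <- stats::runif(3, 0, 2)
    yb <- stats::runif(4, 0, 1)
    da <- f_a(0, ya, NULL)[[1]]
    dab <- f_ab(0, c(ya, yb), NULL)[[1]]
    expect_equal(dab[1:3], da, tolerance = 1e-12)
  }
})

test_that("with zero synthesis every species decays to its basal level", {
  circ <- circuit_spec(
    species = data.frame(name = "p", initial = 2),
    gates = list(gate_node("p", "BUFFER", gate_kinetics(0, 0.7, rho0 = 0.14),
                           list(regulator("u", 0.5, 4)))),
    sources = c(u = 3))
  tr <- simulate_circuit(circ, solver_settings(30, dt_output = 0.1))
  basal <- 0.14 / 0.7
  expect_equal(tr$p, basal + (2 - basal) * exp(-0.7 * tr$time), tolerance = 1e-6)
})

test_that("chi placement conventions behave as documented", {
  # whole-rhs scaling is a pure time rescaling: period * chi is constant
  sweep <- cached("chi_sweep", {
    chi_period_sweep(c(0.3, 0.5, 0.8, 1.0), settings = solver_settings(500))
  })
  expect_true(all(sweep$oscillatory))
  expect_true(all(diff(sweep$period) < 0))  # smaller chi -> longer period
  prods <- sweep$period * sweep$chi
  expect_lt(max(prods) - min(prods), 0.01 * mean(prods))
  # synthesis-only scaling changes the fixed point instead; at chi = 0.5 the
  # ring settles without sustained oscillation
  tr <- simulate_circuit(build_repressilator(chi = 0.5, chi_scaling = "synthesis"),
                         solver_settings(500, dt_output = 0.05))
  expect_error(measure_period(tr, "p_cI"), class = "geneclock_no_oscillation_error")
  # trajectory from the printed initials stays strictly positive (default)
  trw <- repressilator_trace()
  expect_true(all(as.matrix(trw[, -1]) > 0))
})
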