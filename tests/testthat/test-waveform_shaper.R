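unit_template <- function() shaper_stage(hill_input(0.5, 4), gate_kinetics(1, 1, 0))

test_that("analytic threshold hits its closed-form landmarks", {
  ref <- reference_oscillation(A = 0.63, T0 = 32, yd0 = 1.1731)
  expect_equal(analytic_threshold(ref, 0.5), 1.1731)
  expect_equal(analytic_threshold(ref, 1e-9), 1.1731 + 0.63, tolerance = 1e-8)
  expect_equal(analytic_threshold(ref, 1), 1.1731 - 0.63)
  expect_equal(analytic_threshold(ref, 0.1), 1.7723, tolerance = 1e-4)
  # continuous and strictly decreasing in D
  D <- seq(0.01, 1, by = 0.01)
  y <- vapply(D, analytic_threshold, numeric(1), ref = ref)
  expect_true(all(diff(y) < 0))
  expect_lt(max(abs(diff(y))), 0.04)
  expect_error(analytic_threshold(ref, 0), class = "geneclock_domain_error")
  expect_error(reference_oscillation(A = 1, T0 = 32, yd0 = 0.5),
               class = "geneclock_domain_error")
})

test_that("empirical threshold matches the analytic one on a sinusoid", {
  # 320 s span: the steady window holds a whole number of cycles, so the
  # time-quantile is unbiased
  tr <- make_sine_trace(T0 = 32, A = 0.63, yd0 = 1.1731, t_end = 320)
  ref <- reference_oscillation(A = 0.63, T0 = 32, yd0 = 1.1731)
  for (D in c(0.1, 0.5, 0.9)) {
    expect_equal(empirical_threshold(tr, "y", D), analytic_threshold(ref, D),
                 tolerance = 1e-3)
  }
  # decreasing in D; D = 1 is at (or below) the steady minimum
  expect_gt(empirical_threshold(tr, "y", 0.1), empirical_threshold(tr, "y", 0.9))
  w <- steady_window(tr)
  expect_lte(empirical_threshold(tr, "y", 1), min(w$y))
  short <- as_circuit_trace(as.data.frame(tr[tr$time <= 40, ]))
  expect_error(empirical_threshold(short, "y", 0.5),
               class = "geneclock_insufficient_data_error")
})

test_that("cascade design follows the half-maximum threshold recursion", {
  d <- design_cascade(1.76, unit_template(), 5L)
  expect_equal(vapply(d$stages, function(s) s$hill$K, numeric(1)),
               c(1.76, 0.5, 0.5, 0.5, 0.5))
  d2 <- design_cascade(0.6761, unit_template(), 5L)
  expect_equal(d2$stages[[1]]$hill$K, 0.6761)
  # rho = 2 template pushes downstream thresholds to 1.0
  t2 <- shaper_stage(hill_input(1, 4), gate_kinetics(2, 1, 0))
  expect_equal(design_cascade(1.3, t2, 3L)$stages[[2]]$hill$K, 1.0)
  # inconsistent template K is a design error
  bad <- shaper_stage(hill_input(0.7, 4), gate_kinetics(1, 1, 0))
  expect_error(design_cascade(1.3, bad, 3L), class = "geneclock_design_error")
  expect_error(design_cascade(1.3, unit_template(), 1L),
               class = "geneclock_design_error")
})

test_that("gain report flags sub-unity stages without rejecting the design", {
  d <- shaper_reference_design("pulse10")
  expect_warning(rep <- check_gain_condition(d), "gain <= 1")
  expect_equal(rep$gain[2:5], rep(2, 4))
  expect_true(all(rep$pass[2:5]))
  expect_equal(rep$gain[1], 4 / (4 * 1.76), tolerance = 1e-12)
  expect_false(rep$pass[1])
  # exact boundary gain = 1 is still flagged
  db <- design_cascade(1, unit_template(), 2L)
  db$stages <- lapply(db$stages, function(s) { s$hill <- hill_input(1, 4); s })
  expect_warning(rb <- check_gain_condition(db), "gain <= 1")
  expect_equal(rb$gain, c(1, 1))
})

test_that("compensation rate rescales the final stage to the target level", {
  d <- design_cascade(1.76, unit_template(), 5L)
  # if the last stage's high already maps to the target, the rate is gamma
  K <- 0.5; n <- 4
  f <- function(u) (u / K)^n / (1 + (u / K)^n)
  u_high <- 0.9
  expect_equal(compensation_rate(d, u_high, f(u_high)), 1.0)
  expect_equal(compensation_rate(d, 0.92, 1.0), 1 / f(0.92))
  expect_error(compensation_rate(d, 0.4, 1.0), class = "geneclock_infeasible_error")
  dd <- with_compensation(d, 1.0872)
  expect_equal(dd$compensation$kinetics$rho, 1.0872)
  expect_equal(dd$compensation$hill$K, 0.5)
})

test_that("pwm circuit construction reproduces the reference cascades", {
  osc <- build_repressilator(chi = 0.5)
  c10 <- build_pwm_circuit(osc, "p_cI", shaper_reference_design("pulse10"))
  expect_equal(nrow(c10$species), 9L)
  expect_equal(c10$species$name[4:9], paste0("p", 1:6))
  g <- c10$gates[4:9]
  expect_equal(vapply(g, `[[`, character(1), "kind"), rep("BUFFER", 6))
  expect_equal(vapply(g, function(x) x$regulators[[1]]$source, character(1)),
               c("p_cI", paste0("p", 1:5)))
  expect_equal(vapply(g, function(x) x$regulators[[1]]$hill$K, numeric(1)),
               c(1.76, rep(0.5, 5)))
  expect_equal(vapply(g, function(x) x$kinetics$rho, numeric(1)),
               c(rep(1, 5), 1.0872))
  cdc <- build_pwm_circuit(osc, "p_cI", shaper_reference_design("dc"))
  expect_equal(nrow(cdc$species), 7L)
  expect_equal(vapply(cdc$gates[4:7], function(x) x$kinetics$rho, numeric(1)),
               c(1, 1, 1, 1.0851))
  # empty design is the identity
  empty <- structure(list(stages = list(), threshold_first = NA,
                          compensation = NULL), class = "shaper_design")
  expect_identical(build_pwm_circuit(osc, "p_cI", empty), osc)
  expect_error(build_pwm_circuit(osc, "p_zz", shaper_reference_design("dc")),
               class = "geneclock_wiring_error")
})

test_that("shaped pulses stay frequency-coherent with the oscillator", {
  for (type in c("pulse10", "pulse90")) {
    tr <- shaper_trace(type)
    expect_equal(measure_period(tr, "p6"), measure_period(tr, "p_cI"),
                 tolerance = 0.01)
  }
})

test_that("duty decreases with the first-stage threshold and brackets the references", {
  d10 <- measure_duty_cycle(shaper_trace("pulse10"), "p6")
  d90 <- measure_duty_cycle(shaper_trace("pulse90"), "p6")
  ddc <- measure_duty_cycle(shaper_trace("dc"), "p4")
  expect_lt(d10, 0.5)
  expect_gt(d90, 0.5)
  expect_lt(d10, d90)
  expect_equal(ddc, 1.0)
})

test_that("each stage sharpens the waveform (transition time non-increasing)", {
  tr <- steady_window(shaper_trace("pulse90"))
  trans_frac <- function(x) {
    lo <- min(x) + 0.1 * (max(x) - min(x))
    hi <- min(x) + 0.9 * (max(x) - min(x))
    mean(x > lo & x < hi)
  }
  fr <- vapply(c("p_cI", paste0("p", 1:5)), function(s) trans_frac(tr[[s]]),
               numeric(1))
  expect_true(all(diff(fr) <= 0.015))
  expect_lt(fr["p5"], fr["p_cI"])
})
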