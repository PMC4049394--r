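# Shared fixtures. Simulations used by several test files are cached per
# session so the suite stays fast.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

# Synthetic sinusoid trace y = A sin(2*pi*t/T0 + phi) + yd0.
make_sine_trace <- function(T0 = 32, A = 0.63, yd0 = 1.1731, phi = 0,
                            t_end = 500, dt = 0.01, signal = "y") {
  t <- seq(0, t_end, by = dt)
  df <- data.frame(time = t)
  df[[signal]] <- A * sin(2 * pi * t / T0 + phi) + yd0
  as_circuit_trace(df)
}

# Trace of a drive function sampled on a grid.
make_drive_trace <- function(drive, t_end = 500, dt = 0.01, signal = "y") {
  t <- seq(0, t_end, by = dt)
  df <- data.frame(time = t)
  df[[signal]] <- vapply(t, drive$fun, numeric(1))
  as_circuit_trace(df)
}

# The chi = 0.5 repressilator trace used throughout.
repressilator_trace <- function() {
  cached("rep_chi05", {
    simulate_circuit(build_repressilator(chi = 0.5), solver_settings(500))
  })
}

# Repressilator + reference shaper cascade traces.
shaper_trace <- function(type) {
  cached(paste0("shaper_", type), {
    osc <- build_repressilator(chi = 0.5)
    circ <- build_pwm_circuit(osc, "p_cI", shaper_reference_design(type))
    simulate_circuit(circ, solver_settings(500))
  })
}

# --- independent digital JK oracle ----------------------------------------
# Four-state JK next-state rule: hold / reset / set / toggle for
# (J,K) = (0,0) / (0,1) / (1,0) / (1,1).
digital_jk_next <- function(J, K, q) {
  if (J == 0 && K == 0) q
  else if (J == 0 && K == 1) 0L
  else if (J == 1 && K == 0) 1L
  else 1L - q
}

# State after each of n_edges clock edges, starting from q0.
digital_jk_sequence <- function(J, K, q0, n_edges) {
  q <- q0
  out <- integer(n_edges)
  for (i in seq_len(n_edges)) {
    q <- digital_jk_next(J, K, q)
    out[i] <- q
  }
  out
}

# Discretise an ODE flip-flop output against the 0.5 logic threshold at the
# given sample times.
discretise_at <- function(trace, signal, at, threshold = 0.5) {
  x <- stats::approx(trace$time, trace[[signal]], xout = at)$y
  as.integer(x >= threshold)
}

# Simulate one ODE JK flip-flop with constant J/K and an idealised square
# clock; returns the trace. Rising variant gets a narrow (duty 0.1) pulse,
# falling variant a wide (duty 0.9) one.
simulate_jk <- function(edge, J, K, q0, n_cycles = 8, period = 32) {
  build <- if (edge == "rising") build_jk_rising else build_jk_falling
  ff <- build(j_src = J, k_src = K, clk_src = "clk")
  ff$species$initial[ff$species$name == "ff.Q"] <- q0
  ff$species$initial[ff$species$name == "ff.Qb"] <- 1 - q0
  duty <- if (edge == "rising") 0.1 else 0.9
  ff <- add_drive(ff, "clk", square_drive(period = period, duty = duty))
  simulate_circuit(ff, solver_settings((n_cycles + 1) * period, dt_output = 0.05))
}
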