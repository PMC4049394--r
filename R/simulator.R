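#' Solver settings for circuit simulation
#'
#' Defaults target sub-grid accuracy for 32 s-period clock signals: a 0.01 s
#' output grid gives at least 3200 samples per cycle, so duty-cycle
#' quantisation error stays below 0.1 percentage point, and tolerances
#' `rtol = 1e-8`, `atol = 1e-10` keep the integration error well below the
#' metric tolerances used elsewhere.
#'
#' @param t_end End time of the simulation, > 0 (start is 0).
#' @param dt_output Output grid spacing, > 0.
#' @param rtol,atol Relative/absolute integration tolerances, > 0.
#' @param method Integration method passed to [deSolve::ode()]; the default
#'   `"lsoda"` switches automatically between stiff and non-stiff steppers.
#'   Results must be method-independent within tolerance.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(t_end, dt_output = 0.01,
                            rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  if (!is.finite(t_end) || t_end <= 0) .gc_stop("t_end must be > 0", "geneclock_domain_error")
  if (dt_output <= 0) .gc_stop("dt_output must be > 0", "geneclock_domain_error")
  if (rtol <= 0 || atol <= 0) .gc_stop("tolerances must be > 0", "geneclock_domain_error")
  structure(list(t_end = t_end, dt_output = dt_output, rtol = rtol,
                 atol = atol, method = method),
            class = "solver_settings")
}

#' Mark a data frame as a simulation trace
#'
#' A trace is a data frame whose first column `time` is strictly increasing
#' and whose remaining columns are per-signal concentration series. Used by
#' all metric functions; [simulate_circuit()] produces one, and traces can
#' also be built directly (e.g. synthetic sinusoids in tests) or read back
#' from CSV with [read_trace()].
#'
#' @param df A data frame containing a `time` column.
#' @return The data frame with class `circuit_trace`.
#' @export
as_circuit_trace <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"time" %in% names(df)) {
    .gc_stop("a trace needs a 'time' column", "geneclock_parse_error")
  }
  if (nrow(df) > 1 && any(diff(df$time) <= 0)) {
    .gc_stop("trace times must be strictly increasing", "geneclock_domain_error")
  }
  df <- df[, c("time", setdiff(names(df), "time")), drop = FALSE]
  class(df) <- c("circuit_trace", "data.frame")
  df
}

#' Signal names carried by a trace
#' @param trace A `circuit_trace`.
#' @return Character vector of signal (column) names, excluding `time`.
#' @export
trace_signals <- function(trace) setdiff(names(trace), "time")

.trace_signal <- function(trace, signal) {
  if (!signal %in% names(trace)) {
    .gc_stop(paste("trace has no signal named", signal), "geneclock_domain_error")
  }
  as.numeric(trace[[signal]])
}

#' Simulate a circuit
#'
#' Compiles the circuit with [compile_rhs()] and integrates it with
#' [deSolve::ode()] on a uniform output grid. External drives are sampled
#' onto the grid and appended as additional trace columns. Small negative
#' solver undershoots are clipped to zero in the reported trace only (the
#' raw solver state is untouched during integration).
#'
#' @param circuit A valid [circuit_spec()].
#' @param settings A [solver_settings()].
#' @return A `circuit_trace` data frame: `time`, one column per species (in
#'   declaration order), then one column per drive.
#' @export
simulate_circuit <- function(circuit, settings) {
  stopifnot(inherits(circuit, "circuit_spec"), inherits(settings, "solver_settings"))
  compiled <- compile_rhs(circuit)
  y0 <- stats::setNames(circuit$species$initial, compiled$species)
  times <- seq(0, settings$t_end, by = settings$dt_output)
  out <- deSolve::ode(y = y0, times = times, func = compiled$fun, parms = NULL,
                      method = settings$method,
                      rtol = settings$rtol, atol = settings$atol)
  m <- unclass(out)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!stats::complete.cases(m) | rowSums(!is.finite(m)) > 0)[1]
    .gc_stop(sprintf("integration failed near t = %.6g", m[bad, 1]),
             "geneclock_integration_error")
  }
  if (nrow(m) < length(times)) {
    .gc_stop(sprintf("integration stopped early at t = %.6g", m[nrow(m), 1]),
             "geneclock_integration_error")
  }
  df <- as.data.frame(m)
  names(df)[1] <- "time"
  for (j in seq_along(df)[-1]) df[[j]] <- pmax(df[[j]], 0)
  for (dn in names(circuit$drives)) {
    df[[dn]] <- vapply(df$time, circuit$drives[[dn]]$fun, numeric(1))
  }
  as_circuit_trace(df)
}

#' Drop the initial transient of a trace
#'
#' Returns the suffix of the trace after discarding the leading fraction of
#' the simulated time span. All metric functions use a default discard of
#' 0.3, a conservative allowance for the few settling cycles the circuits
#' here need.
#'
#' @param trace A `circuit_trace`.
#' @param discard_fraction Fraction of the time span to drop, in `[0, 1)`.
#' @return The truncated `circuit_trace`.
#' @export
steady_window <- function(trace, discard_fraction = 0.3) {
  stopifnot(inherits(trace, "circuit_trace"))
  if (!is.finite(discard_fraction) || discard_fraction < 0 || discard_fraction >= 1) {
    .gc_stop("discard_fraction must be in [0, 1)", "geneclock_window_error")
  }
  if (discard_fraction == 0) return(trace)
  t0 <- trace$time[1]
  t1 <- trace$time[nrow(trace)]
  keep <- trace$time >= t0 + discard_fraction * (t1 - t0)
  if (!any(keep)) .gc_stop("steady window is empty", "geneclock_window_error")
  as_circuit_trace(trace[keep, , drop = FALSE])
}
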