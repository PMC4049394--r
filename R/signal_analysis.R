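# Shared helpers ------------------------------------------------------------

# Steady-window values of one signal.
.steady_xy <- function(trace, signal, discard) {
  w <- steady_window(trace, discard)
  list(t = w$time, x = .trace_signal(w, signal))
}

# Relative swing used to classify a signal as non-oscillatory.
.rel_swing <- function(x) {
  lev <- max(abs((max(x) + min(x)) / 2), .Machine$double.eps)
  (max(x) - min(x)) / lev
}

# One refined peak time per cycle. Cycles are delimited by hysteresis-filtered
# upward crossings of the mid-range level, so solver ripple on flat pulse tops
# cannot create spurious cycles; within each cycle the discrete maximum is
# refined by a 3-point quadratic fit.
.peak_times <- function(t, x, hysteresis = 0.05) {
  thr <- (max(x) + min(x)) / 2
  band <- hysteresis * (max(x) - min(x))
  up <- .hysteresis_crossings(t, x, thr, band)$rising_idx
  if (length(up) < 2L) return(numeric())
  pk <- numeric(0)
  for (k in seq_len(length(up) - 1L)) {
    seg <- up[k]:up[k + 1L]
    j <- seg[which.max(x[seg])]
    pk <- c(pk, .refine_peak(t, x, j))
  }
  pk
}

.refine_peak <- function(t, x, j) {
  n <- length(x)
  if (j <= 1L || j >= n) return(t[j])
  den <- x[j - 1L] - 2 * x[j] + x[j + 1L]
  if (den >= 0) return(t[j])
  delta <- 0.5 * (x[j - 1L] - x[j + 1L]) / den
  t[j] + delta * (t[j + 1L] - t[j])
}

# Hysteresis state machine, vectorised via constant interpolation: a sample is
# committed "high" above thr + band/2, "low" below thr - band/2, otherwise it
# keeps the previous committed state. Returns sample indices at which the
# committed state flips.
.hysteresis_crossings <- function(t, x, thr, band) {
  hi <- thr + band / 2
  lo <- thr - band / 2
  s <- rep(NA_real_, length(x))
  s[x >= hi] <- 1
  s[x <= lo] <- 0
  known <- which(!is.na(s))
  if (length(known) == 0L) {
    return(list(rising_idx = integer(), falling_idx = integer(), state = NULL))
  }
  if (known[1] > 1L) s[1] <- as.numeric(x[1] >= thr)
  filled <- stats::approx(x = which(!is.na(s)), y = s[!is.na(s)],
                          xout = seq_along(s), method = "constant",
                          rule = 2, f = 0)$y
  d <- diff(filled)
  list(rising_idx = which(d == 1) + 1L,
       falling_idx = which(d == -1) + 1L,
       state = filled)
}

#' Measure the oscillation period of a trace signal
#'
#' Mean spacing of successive cycle maxima in the steady window. Peak times
#' are localised to sub-grid precision with a 3-point quadratic fit around
#' each discrete maximum; one maximum is taken per cycle (cycles delimited by
#' mid-range upward crossings with a hysteresis band), so a 0.01 s grid
#' resolves a 32 s period to well under one grid step.
#'
#' @param trace A `circuit_trace`.
#' @param signal Signal (column) name.
#' @param discard Transient fraction to drop first (see [steady_window()]).
#' @return The period (time units).
#' @export
measure_period <- function(trace, signal, discard = 0.3) {
  s <- .steady_xy(trace, signal, discard)
  if (.rel_swing(s$x) < 0.01) {
    .gc_stop(paste("signal", signal, "does not oscillate (swing < 1% of level)"),
             "geneclock_no_oscillation_error")
  }
  pk <- .peak_times(s$t, s$x)
  if (length(pk) < 3L) {
    .gc_stop("fewer than 3 steady-window maxima; simulate longer",
             "geneclock_insufficient_data_error")
  }
  mean(diff(pk))
}

#' Measure steady amplitude and base level
#'
#' `amplitude` is half the steady peak-to-trough swing, `base_level` the
#' mid peak-trough level. A constant signal returns amplitude 0 and its own
#' level, without error.
#'
#' @inheritParams measure_period
#' @return Named numeric vector `c(amplitude, base_level)`.
#' @export
measure_amplitude_base <- function(trace, signal, discard = 0.3) {
  s <- .steady_xy(trace, signal, discard)
  c(amplitude = (max(s$x) - min(s$x)) / 2,
    base_level = (max(s$x) + min(s$x)) / 2)
}

#' Measure the duty cycle of a trace signal
#'
#' Fraction of steady-window time the signal spends at or above a threshold,
#' with threshold crossings interpolated between samples. By default the
#' threshold is the mid-range level (midpoint of steady min/max) - a
#' symmetric, parameter-free choice for pulse-like signals. A signal whose
#' steady swing is below 5% of its level is classified as a direct-current
#' (logic-steady) level rather than a pulse: with the default threshold it
#' reports duty 1.0 (the convention for a rectified, always-high output);
#' with an explicit threshold the comparison is taken literally.
#'
#' @inheritParams measure_period
#' @param threshold Optional explicit threshold level.
#' @return Duty fraction in `[0, 1]`.
#' @export
measure_duty_cycle <- function(trace, signal, threshold = NULL, discard = 0.3) {
  s <- .steady_xy(trace, signal, discard)
  if (is.null(threshold)) {
    if (.rel_swing(s$x) < 0.05) return(1.0)
    threshold <- (max(s$x) + min(s$x)) / 2
  }
  if (all(s$x >= threshold)) return(1.0)
  if (all(s$x < threshold)) return(0.0)
  .duty_fraction(s$t, s$x, threshold)
}

#' Detect rising and falling edges of a trace signal
#'
#' Finds interpolated threshold-crossing times, using a hysteresis band (a
#' fraction of the steady swing, default 5%) so that solver ripple near the
#' threshold cannot produce chatter. Edges strictly alternate.
#'
#' @inheritParams measure_duty_cycle
#' @param hysteresis Band width as a fraction of the steady swing.
#' @return A list with numeric vectors `rising` and `falling` (times).
#' @export
detect_edges <- function(trace, signal, threshold = NULL, hysteresis = 0.05,
                         discard = 0.3) {
  s <- .steady_xy(trace, signal, discard)
  swing <- max(s$x) - min(s$x)
  if (swing <= 0) return(list(rising = numeric(), falling = numeric()))
  if (is.null(threshold)) threshold <- (max(s$x) + min(s$x)) / 2
  if (threshold < min(s$x) || threshold > max(s$x)) {
    .gc_stop("threshold outside the signal range", "geneclock_domain_error")
  }
  cr <- .hysteresis_crossings(s$t, s$x, threshold, hysteresis * swing)
  locate <- function(i, rising) {
    # walk back from the committed sample to the actual threshold crossing
    j <- i - 1L
    while (j > 1L && ((rising && s$x[j] >= threshold) ||
                      (!rising && s$x[j] < threshold))) {
      j <- j - 1L
    }
    x0 <- s$x[j]; x1 <- s$x[j + 1L]
    if (x1 == x0) return(s$t[j])
    lam <- (threshold - x0) / (x1 - x0)
    s$t[j] + lam * (s$t[j + 1L] - s$t[j])
  }
  list(rising = vapply(cr$rising_idx, locate, numeric(1), rising = TRUE),
       falling = vapply(cr$falling_idx, locate, numeric(1), rising = FALSE))
}

#' Summary metrics of one trace signal
#'
#' Convenience wrapper returning period, amplitude, base level, duty cycle
#' and edge times in one object. Period is `NA` for non-oscillatory signals.
#'
#' @inheritParams detect_edges
#' @return A `signal_metrics` list.
#' @export
signal_metrics <- function(trace, signal, threshold = NULL, discard = 0.3) {
  ab <- measure_amplitude_base(trace, signal, discard)
  per <- tryCatch(measure_period(trace, signal, discard),
                  geneclock_no_oscillation_error = function(e) NA_real_,
                  geneclock_insufficient_data_error = function(e) NA_real_)
  edges <- tryCatch(detect_edges(trace, signal, threshold, discard = discard),
                    geneclock_error = function(e) list(rising = numeric(),
                                                       falling = numeric()))
  structure(list(signal = signal,
                 period = per,
                 amplitude = unname(ab["amplitude"]),
                 base_level = unname(ab["base_level"]),
                 duty_cycle = measure_duty_cycle(trace, signal, threshold, discard),
                 rising_edges = edges$rising,
                 falling_edges = edges$falling),
            class = "signal_metrics")
}

#' @export
print.signal_metrics <- function(x, ...) {
  cat(sprintf("<signal_metrics> %s\n", x$signal))
  cat(sprintf("  period      %s\n", format(x$period)))
  cat(sprintf("  amplitude   %s\n", format(x$amplitude)))
  cat(sprintf("  base_level  %s\n", format(x$base_level)))
  cat(sprintf("  duty_cycle  %s\n", format(x$duty_cycle)))
  cat(sprintf("  edges       %d rising / %d falling\n",
              length(x$rising_edges), length(x$falling_edges)))
  invisible(x)
}

#' Period of the repressilator across regulation coefficients
#'
#' Builds and simulates one repressilator per `chi` value and measures the
#' steady period of the tapped species. Non-oscillatory entries are flagged,
#' not fatal. Under the default whole-rhs `chi` placement the product
#' `period * chi` is constant (pure time rescaling), so the period increases
#' as `chi` decreases.
#'
#' @param chis Numeric vector of regulation coefficients, all > 0.
#' @param signal Species to measure (default `"p_cI"`).
#' @param settings [solver_settings()] for each run.
#' @param ... Passed to [build_repressilator()] (e.g. `chi_scaling`).
#' @return A data frame with columns `chi`, `period`, `oscillatory`.
#' @export
chi_period_sweep <- function(chis, signal = "p_cI",
                             settings = solver_settings(500), ...) {
  stopifnot(all(chis > 0))
  rows <- lapply(chis, function(ch) {
    tr <- simulate_circuit(build_repressilator(chi = ch, ...), settings)
    per <- tryCatch(measure_period(tr, signal),
                    geneclock_no_oscillation_error = function(e) NA_real_,
                    geneclock_insufficient_data_error = function(e) NA_real_)
    data.frame(chi = ch, period = per, oscillatory = is.finite(per))
  })
  do.call(rbind, rows)
}
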