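#' Square-wave external drive
#'
#' An idealised clock signal used to drive circuits (e.g. to exercise a
#' flip-flop independently of the waveform shaper). The wave is periodic with
#' a linear rise/fall of duration `t_rise` (a perfectly discontinuous square
#' would needlessly stress the integrator; 0.2 s against a 32 s period is
#' sharp on the circuit's time scale).
#'
#' The high window starts at each multiple of `period` (shifted by `phase`)
#' and lasts `duty * period`.
#'
#' @param period Wave period (time units), > 0.
#' @param duty High-time fraction in (0, 1).
#' @param high,low Levels of the two plateaus.
#' @param t_rise Edge rise/fall duration, >= 0.
#' @param phase Time shift applied to the wave.
#' @return A `circuit_drive` object (list with `type`, `pars`, `fun`).
#' @export
square_drive <- function(period, duty, high = 1, low = 0,
                         t_rise = 0.2, phase = 0) {
  if (period <= 0) .gc_stop("period must be > 0", "geneclock_domain_error")
  if (duty <= 0 || duty >= 1) .gc_stop("duty must be in (0, 1)", "geneclock_domain_error")
  if (t_rise < 0 || t_rise > duty * period) {
    .gc_stop("t_rise must be in [0, duty * period]", "geneclock_domain_error")
  }
  pars <- list(period = period, duty = duty, high = high, low = low,
               t_rise = t_rise, phase = phase)
  fun <- function(t) {
    ph <- (t - phase) %% period
    w <- duty * period
    v <- if (t_rise > 0 && ph < t_rise) {
      ph / t_rise
    } else if (ph < w) {
      1
    } else if (t_rise > 0 && ph < w + t_rise) {
      1 - (ph - w) / t_rise
    } else 0
    low + (high - low) * v
  }
  structure(list(type = "square", pars = pars, fun = fun),
            class = "circuit_drive")
}

#' Attach an external drive to a circuit
#'
#' Adds a named time signal to the circuit. If the name was declared as a
#' free input it is thereby bound.
#'
#' @param circuit A [circuit_spec()].
#' @param name Signal name the drive provides.
#' @param drive A drive object, e.g. from [square_drive()].
#' @return The updated [circuit_spec()].
#' @export
add_drive <- function(circuit, name, drive) {
  stopifnot(inherits(circuit, "circuit_spec"), inherits(drive, "circuit_drive"))
  .gc_check_name(name, "drive name")
  taken <- c(circuit$species$name, names(circuit$sources), names(circuit$drives))
  if (name %in% taken) {
    .gc_stop(paste("name already in use:", name), "geneclock_naming_error")
  }
  circuit$drives[[name]] <- drive
  circuit$inputs <- setdiff(circuit$inputs, name)
  circuit
}
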