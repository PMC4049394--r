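#' Reference oscillation (sinusoid) parameters
#'
#' The idealised clock source `y(t) = A * sin(omega0 * t + phi) + yd0` with
#' amplitude `A`, basal period `T0` (`omega0 = 2*pi/T0`), phase `phi`, and
#' base level `yd0 >= A` so the signal stays non-negative.
#'
#' @param A Amplitude, > 0.
#' @param T0 Basal period, > 0.
#' @param phi Phase (radians).
#' @param yd0 Base level, >= `A`.
#' @return A `reference_oscillation` object.
#' @export
reference_oscillation <- function(A, T0, phi = 0, yd0) {
  if (A <= 0) .gc_stop("amplitude A must be > 0", "geneclock_domain_error")
  if (T0 <= 0) .gc_stop("basal period T0 must be > 0", "geneclock_domain_error")
  if (yd0 < A) .gc_stop("base level yd0 must be >= A (non-negative signal)",
                        "geneclock_domain_error")
  structure(list(A = A, T0 = T0, omega0 = 2 * pi / T0, phi = phi, yd0 = yd0),
            class = "reference_oscillation")
}

.check_duty <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0 || D > 1) {
    .gc_stop("duty cycle D must be in (0, 1]", "geneclock_domain_error")
  }
  D
}

#' Threshold for a target duty cycle on a sinusoid
#'
#' For the reference sinusoid, the level exceeded during exactly the
#' fraction `D` of each cycle, centred on the peak: evaluating the sinusoid
#' half an on-time either side of its peak gives
#' `y_T = yd0 + A * cos(pi * D)`. It is continuous and strictly decreasing
#' in `D`: `D -> 0` approaches `yd0 + A`, `D = 0.5` gives the base level,
#' and `D = 1` gives `yd0 - A`.
#'
#' @param ref A [reference_oscillation()].
#' @param D Target duty cycle in (0, 1].
#' @return The threshold level `y_T`.
#' @export
analytic_threshold <- function(ref, D) {
  stopifnot(inherits(ref, "reference_oscillation"))
  .check_duty(D)
  ref$yd0 + ref$A * cos(pi * D)
}

#' Threshold for a target duty cycle from a simulated trace
#'
#' The repressilator waveform is not sinusoidal, so the closed-form
#' threshold of [analytic_threshold()] is biased on real traces. This
#' variant returns the steady-window time-quantile: the level above which
#' the signal spends exactly the fraction `D` of its time. It is decreasing
#' in `D`, and for `D = 1` returns the steady minimum.
#'
#' @param trace A `circuit_trace` containing at least 3 steady cycles of
#'   `signal`.
#' @param signal Signal name.
#' @param D Target duty cycle in (0, 1].
#' @param discard Transient fraction to drop.
#' @return The threshold level.
#' @export
empirical_threshold <- function(trace, signal, D, discard = 0.3) {
  .check_duty(D)
  s <- .steady_xy(trace, signal, discard)
  if (.rel_swing(s$x) < 0.01 || length(.peak_times(s$t, s$x)) < 3L) {
    .gc_stop("need at least 3 steady cycles to place an empirical threshold",
             "geneclock_insufficient_data_error")
  }
  stats::quantile(s$x, probs = 1 - D, names = FALSE, type = 7)
}

#' One Buffer stage of a waveform-shaping cascade
#'
#' @param hill A [hill_input()]: the stage threshold `K` and steepness `n`.
#' @param kinetics A [gate_kinetics()].
#' @return A `shaper_stage` object.
#' @export
shaper_stage <- function(hill, kinetics) {
  stopifnot(inherits(hill, "hill_input"), inherits(kinetics, "gate_kinetics"))
  structure(list(hill = hill, kinetics = kinetics), class = "shaper_stage")
}

# threshold the NEXT stage must use: half the maximal steady output
.next_threshold <- function(stage) {
  k <- stage$kinetics
  (k$rho + k$rho0) / (2 * k$gamma)
}

#' Design a Buffer cascade for a first-stage threshold
#'
#' Stage 1 thresholds the oscillation at `threshold_first`; every later
#' stage `k` re-thresholds the previous stage's output at half its maximal
#' level, `K_k = (rho_{k-1} + rho0_{k-1}) / (2 * gamma_{k-1})` (so with unit
#' rates and no basal production all downstream thresholds are 0.5). All
#' stages share the template's rates and Hill coefficient; the template's
#' own `K` must equal the recursion value it implies, otherwise the design
#' is inconsistent.
#'
#' @param threshold_first First-stage threshold (`y_T`), > 0.
#' @param stage_template A [shaper_stage()] providing rates and `n`.
#' @param M Number of shaping stages, >= 2.
#' @return A `shaper_design` object (fields `stages`, `threshold_first`,
#'   `compensation`).
#' @seealso [with_compensation()], [build_pwm_circuit()]
#' @export
design_cascade <- function(threshold_first, stage_template, M) {
  stopifnot(inherits(stage_template, "shaper_stage"))
  if (!is.finite(threshold_first) || threshold_first <= 0) {
    .gc_stop("threshold_first must be > 0", "geneclock_domain_error")
  }
  if (M < 2) .gc_stop("a cascade needs at least 2 stages", "geneclock_design_error")
  k_down <- .next_threshold(stage_template)
  if (abs(stage_template$hill$K - k_down) > 1e-9 * max(1, k_down)) {
    .gc_stop(sprintf(paste("inconsistent stage template: downstream thresholds",
                           "must equal (rho + rho0)/(2*gamma) = %.6g, template has K = %.6g"),
                     k_down, stage_template$hill$K),
             "geneclock_design_error")
  }
  n <- stage_template$hill$n
  stages <- c(
    list(shaper_stage(hill_input(threshold_first, n), stage_template$kinetics)),
    rep(list(shaper_stage(hill_input(k_down, n), stage_template$kinetics)), M - 1L)
  )
  structure(list(stages = stages, threshold_first = threshold_first,
                 compensation = NULL),
            class = "shaper_design")
}

#' Per-stage gain report for a cascade design
#'
#' Evaluates each stage's operating-point gain `rho * n / (4 * gamma * K)`
#' (see [buffer_gain()]). Stages whose gain does not exceed 1 cannot sharpen
#' the waveform and are flagged with a warning; the design is not rejected,
#' because a large first-stage threshold (needed for small duty cycles) can
#' make its gain sub-unity while the cascade as a whole still functions.
#'
#' @param design A `shaper_design`.
#' @return A data frame with columns `stage`, `K`, `n`, `rho`, `gamma`,
#'   `gain`, `pass`.
#' @export
check_gain_condition <- function(design) {
  stopifnot(inherits(design, "shaper_design"))
  stages <- design$stages
  if (!is.null(design$compensation)) stages <- c(stages, list(design$compensation))
  rep <- do.call(rbind, lapply(seq_along(stages), function(i) {
    st <- stages[[i]]
    g <- buffer_gain(st$kinetics, st$hill)
    data.frame(stage = i, K = st$hill$K, n = st$hill$n,
               rho = st$kinetics$rho, gamma = st$kinetics$gamma,
               gain = g, pass = g > 1)
  }))
  if (any(!rep$pass)) {
    warning(sprintf("stage(s) %s have operating-point gain <= 1",
                    paste(rep$stage[!rep$pass], collapse = ", ")),
            call. = FALSE)
  }
  rep
}

#' Synthesis rate of a compensation stage
#'
#' A cascade whose first threshold is large converges slowly to the maximal
#' level, so its logic-high plateau falls short of the nominal maximum. A
#' final Buffer is appended whose synthesis rate is chosen so that its
#' steady output at the cascade's actual high level equals the desired
#' level: `rho = gamma * target_high / f_Buffer(input_high; K, n)` (with no
#' basal production), where `K` is the threshold the recursion assigns to
#' the appended stage.
#'
#' @param design A `shaper_design`.
#' @param input_high Logic-high level of the last stage's output; must
#'   exceed the appended stage's threshold.
#' @param target_high Desired logic-high output level.
#' @return The synthesis rate (numeric).
#' @export
compensation_rate <- function(design, input_high, target_high) {
  stopifnot(inherits(design, "shaper_design"))
  last <- design$stages[[length(design$stages)]]
  K <- .next_threshold(last)
  n <- last$hill$n
  if (!is.finite(input_high) || input_high <= K) {
    .gc_stop(sprintf("compensation infeasible: input high %.6g is not above the stage threshold %.6g",
                     input_high, K),
             "geneclock_infeasible_error")
  }
  f <- promoter_activity("BUFFER", list(list(level = input_high, hill = hill_input(K, n))))
  last$kinetics$gamma * target_high / f
}

#' Append a compensation stage to a cascade design
#'
#' @param design A `shaper_design`.
#' @param rate Synthesis rate of the compensation Buffer (e.g. from
#'   [compensation_rate()]).
#' @return The design with its `compensation` stage set.
#' @export
with_compensation <- function(design, rate) {
  stopifnot(inherits(design, "shaper_design"))
  last <- design$stages[[length(design$stages)]]
  design$compensation <- shaper_stage(
    hill_input(.next_threshold(last), last$hill$n),
    gate_kinetics(rho = rate, gamma = last$kinetics$gamma, rho0 = 0))
  design
}

#' Bundled reference shaper designs
#'
#' The three worked waveform-shaping circuits used throughout the package's
#' examples and tests, all with Hill coefficient 4, unit rates and no basal
#' production:
#' \describe{
#'   \item{`"pulse10"`}{first threshold 1.76, five shaping stages, then a
#'     compensation stage with synthesis rate 1.0872 - a narrow clock pulse
#'     (rising-edge trigger source).}
#'   \item{`"pulse90"`}{first threshold 0.6761, rate 1.1083 - a wide pulse
#'     (falling-edge trigger source).}
#'   \item{`"dc"`}{three shaping stages at threshold 0.5, rate 1.0851 - a
#'     rectified always-high (direct-current) output.}
#' }
#'
#' @param type One of `"pulse10"`, `"pulse90"`, `"dc"`.
#' @return A `shaper_design` with compensation stage attached.
#' @export
shaper_reference_design <- function(type = c("pulse10", "pulse90", "dc")) {
  type <- match.arg(type)
  template <- shaper_stage(hill_input(0.5, 4), gate_kinetics(1, 1, 0))
  switch(type,
    pulse10 = with_compensation(design_cascade(1.76, template, 5L), 1.0872),
    pulse90 = with_compensation(design_cascade(0.6761, template, 5L), 1.1083),
    dc      = with_compensation(design_cascade(0.5, template, 3L), 1.0851))
}

#' Wire a shaper design onto an oscillator circuit
#'
#' Appends the cascade's Buffer genes in series to the oscillator: stage 1
#' is activated by the tapped species, each later stage by its predecessor,
#' and the compensation stage (if any) comes last. Stage species are named
#' `p1, p2, ...` by default. An empty design returns the oscillator
#' unchanged.
#'
#' @param oscillator A [circuit_spec()] providing the oscillation.
#' @param tap Species of `oscillator` that feeds the first stage.
#' @param design A `shaper_design`.
#' @param prefix Prefix for the stage species names.
#' @return The combined [circuit_spec()].
#' @export
build_pwm_circuit <- function(oscillator, tap, design, prefix = "p") {
  stopifnot(inherits(oscillator, "circuit_spec"), inherits(design, "shaper_design"))
  if (!tap %in% oscillator$species$name) {
    .gc_stop(paste("tap species not found in oscillator:", tap),
             "geneclock_wiring_error")
  }
  stages <- design$stages
  if (!is.null(design$compensation)) stages <- c(stages, list(design$compensation))
  if (length(stages) == 0L) return(oscillator)
  nm <- paste0(prefix, seq_along(stages))
  gates <- lapply(seq_along(stages), function(k) {
    st <- stages[[k]]
    src <- if (k == 1L) tap else nm[k - 1L]
    gate_node(nm[k], "BUFFER", st$kinetics,
              list(regulator(src, st$hill$K, st$hill$n)))
  })
  shaper <- circuit_spec(species = data.frame(name = nm, initial = 0),
                         gates = gates, inputs = tap)
  cascade(oscillator, shaper, stats::setNames(tap, tap))
}
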