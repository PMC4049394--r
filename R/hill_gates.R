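#' Hill input: binding parameters of one regulator
#'
#' A regulator acting on a promoter is characterised by its Hill constant
#' `K` (the regulator concentration at half-maximal effect, in arbitrary
#' concentration units) and its Hill coefficient `n` (binding cooperativity,
#' dimensionless).
#'
#' @param K Hill constant, > 0.
#' @param n Hill coefficient, > 0. Non-integer values are accepted; the
#'   bundled reference circuits all use `n = 4`.
#' @return An object of class `hill_input`.
#' @examples
#' hill_input(0.5, 4)
#' @export
hill_input <- function(K, n) {
  stopifnot(is.numeric(K), length(K) == 1L, is.numeric(n), length(n) == 1L)
  if (!is.finite(K) || K <= 0) .gc_stop("Hill constant K must be > 0", "geneclock_domain_error")
  if (!is.finite(n) || n <= 0) .gc_stop("Hill coefficient n must be > 0", "geneclock_domain_error")
  structure(list(K = K, n = n), class = "hill_input")
}

#' Lumped protein-level gate kinetics
#'
#' One-equation kinetics of a gate gene: `dp/dt = rho * f(u) - gamma * p +
#' rho0`, where `f` is the promoter activity in `[0, 1]`.
#'
#' @param rho Protein synthesis rate (concentration/time), >= 0.
#' @param gamma Protein decay rate (1/time), > 0.
#' @param rho0 Basal production rate (concentration/time), >= 0.
#' @return An object of class `gate_kinetics`.
#' @export
gate_kinetics <- function(rho, gamma, rho0 = 0) {
  stopifnot(is.numeric(rho), is.numeric(gamma), is.numeric(rho0))
  if (!is.finite(gamma) || gamma <= 0) .gc_stop("decay rate gamma must be > 0", "geneclock_domain_error")
  if (rho < 0 || rho0 < 0) .gc_stop("synthesis rates must be >= 0", "geneclock_domain_error")
  structure(list(rho = rho, gamma = gamma, rho0 = rho0), class = "gate_kinetics")
}

#' Two-stage transcription/translation kinetics
#'
#' Full mRNA + protein model of a gate gene:
#' `dm/dt = alpha * f(u) - lambda * m + alpha0`, `dp/dt = beta * m - gamma * p`.
#'
#' @param alpha mRNA transcription rate, >= 0.
#' @param lambda mRNA decay rate, > 0.
#' @param beta protein synthesis rate per mRNA, >= 0.
#' @param gamma protein decay rate, > 0.
#' @param alpha0 basal transcription rate, >= 0.
#' @return An object of class `txtl_kinetics`.
#' @seealso [reduce_kinetics()] for the quasi-steady-state reduction.
#' @export
txtl_kinetics <- function(alpha, lambda, beta, gamma, alpha0 = 0) {
  if (!is.finite(lambda) || lambda <= 0) .gc_stop("mRNA decay rate lambda must be > 0", "geneclock_domain_error")
  if (!is.finite(gamma) || gamma <= 0) .gc_stop("protein decay rate gamma must be > 0", "geneclock_domain_error")
  if (alpha < 0 || beta < 0 || alpha0 < 0) .gc_stop("rates must be >= 0", "geneclock_domain_error")
  structure(list(alpha = alpha, lambda = lambda, beta = beta,
                 gamma = gamma, alpha0 = alpha0),
            class = "txtl_kinetics")
}

#' Reduce two-stage kinetics to protein-level kinetics
#'
#' Because mRNA half-life is short relative to the protein's, the mRNA
#' equation is eliminated at its quasi steady state, giving lumped rates
#' `rho = alpha * beta / lambda` and `rho0 = alpha0 * beta / lambda` with the
#' protein decay rate unchanged. The reduced model has the same steady states
#' as the full model.
#'
#' @param kin A [txtl_kinetics()] object.
#' @return A [gate_kinetics()] object.
#' @export
reduce_kinetics <- function(kin) {
  stopifnot(inherits(kin, "txtl_kinetics"))
  gate_kinetics(rho = kin$alpha * kin$beta / kin$lambda,
                gamma = kin$gamma,
                rho0 = kin$alpha0 * kin$beta / kin$lambda)
}

GATE_KINDS <- c("NOT", "BUFFER", "AND", "OR", "XOR", "NAND", "NOR")

#' Number of regulators a gate kind takes
#' @param kind One of `"NOT"`, `"BUFFER"`, `"AND"`, `"OR"`, `"XOR"`,
#'   `"NAND"`, `"NOR"`.
#' @return 1 for NOT/BUFFER, 2 for the others.
#' @export
gate_arity <- function(kind) {
  kind <- match.arg(toupper(kind), GATE_KINDS)
  if (kind %in% c("NOT", "BUFFER")) 1L else 2L
}

# (u/K)^n with the u = 0 limit taken as x = 0 (avoids 0^n issues for
# non-integer n when the solver hands in an exact zero).
.hill_x <- function(u, K, n) {
  x <- numeric(length(u))
  pos <- u > 0
  x[pos] <- (u[pos] / K)^n
  x
}

#' Promoter activity of a genetic logic gate
#'
#' Evaluates the normalised promoter activity `f` in `[0, 1]` for the seven
#' gate kinds. One-input gates (NOT, BUFFER) are classic repression /
#' activation Hill functions; the two-input gates combine the occupancy terms
#' `x_i = (u_i/K_i)^n_i` of two operator sites:
#' AND `x1 x2 / Z`, OR `(x1 + x2 + x1 x2)/Z`, XOR `(x1 + x2)/Z`,
#' NAND `(1 + x1 + x2)/Z`, NOR `1/Z`, with `Z = 1 + x1 + x2 + x1 x2`.
#'
#' @param kind Gate kind (see [gate_arity()]).
#' @param regulators A list of one or two `list(level = , hill = )` entries:
#'   `level` is the regulator concentration (>= 0) and `hill` a
#'   [hill_input()].
#' @return The activity fraction, a number in `[0, 1]`.
#' @examples
#' promoter_activity("NOT", list(list(level = 0, hill = hill_input(1, 4))))
#' @export
promoter_activity <- function(kind, regulators) {
  kind <- match.arg(toupper(kind), GATE_KINDS)
  arity <- gate_arity(kind)
  if (length(regulators) != arity) {
    .gc_stop(sprintf("gate kind %s takes %d regulator(s), got %d",
                     kind, arity, length(regulators)), "geneclock_arity_error")
  }
  lv <- vapply(regulators, function(r) as.numeric(r$level), numeric(1))
  if (any(!is.finite(lv)) || any(lv < 0)) {
    .gc_stop("regulator levels must be finite and >= 0", "geneclock_domain_error")
  }
  h <- lapply(regulators, function(r) r$hill)
  x1 <- .hill_x(lv[1], h[[1]]$K, h[[1]]$n)
  if (arity == 1L) {
    switch(kind,
           NOT    = 1 / (1 + x1),
           BUFFER = x1 / (1 + x1))
  } else {
    x2 <- .hill_x(lv[2], h[[2]]$K, h[[2]]$n)
    z <- 1 + x1 + x2 + x1 * x2
    switch(kind,
           AND  = x1 * x2 / z,
           OR   = (x1 + x2 + x1 * x2) / z,
           XOR  = (x1 + x2) / z,
           NAND = (1 + x1 + x2) / z,
           NOR  = 1 / z)
  }
}

#' Rate of change of a gate protein (reduced model)
#'
#' @param kin A [gate_kinetics()] object.
#' @param kind Gate kind.
#' @param regulators As in [promoter_activity()].
#' @param p Current protein concentration, >= 0.
#' @return `rho * f - gamma * p + rho0`.
#' @export
reduced_gate_rhs <- function(kin, kind, regulators, p) {
  stopifnot(inherits(kin, "gate_kinetics"), p >= 0)
  f <- promoter_activity(kind, regulators)
  kin$rho * f - kin$gamma * p + kin$rho0
}

#' Rate of change of mRNA and protein (two-stage model)
#'
#' @param kin A [txtl_kinetics()] object.
#' @param kind Gate kind.
#' @param regulators As in [promoter_activity()].
#' @param m Current mRNA concentration, >= 0.
#' @param p Current protein concentration, >= 0.
#' @return A named numeric vector `c(dm, dp)`.
#' @export
full_gate_rhs <- function(kin, kind, regulators, m, p) {
  stopifnot(inherits(kin, "txtl_kinetics"), m >= 0, p >= 0)
  f <- promoter_activity(kind, regulators)
  c(dm = kin$alpha * f - kin$lambda * m + kin$alpha0,
    dp = kin$beta * m - kin$gamma * p)
}

#' Steady-state output of a genetic Buffer
#'
#' The Buffer's steady output for a constant input `u` is
#' `(rho/gamma) * f_Buffer(u; K, n) + rho0/gamma`; the second term is the
#' minimal level and `rho/gamma` the swing between minimal and maximal level.
#' The output is half-way between those limits at `u = K`, which is why the
#' Hill constant of a Buffer stage plays the role of its threshold level.
#'
#' @param kin A [gate_kinetics()] object.
#' @param hill A [hill_input()] object.
#' @param u Input concentration, >= 0 (vectorised).
#' @return Steady-state concentration(s).
#' @export
buffer_steady_state <- function(kin, hill, u) {
  stopifnot(inherits(kin, "gate_kinetics"), inherits(hill, "hill_input"))
  if (any(u < 0)) .gc_stop("input concentration must be >= 0", "geneclock_domain_error")
  x <- .hill_x(u, hill$K, hill$n)
  (kin$rho / kin$gamma) * (x / (1 + x)) + kin$rho0 / kin$gamma
}

#' Buffer gain at the operating point
#'
#' Slope of the Buffer's steady-state input/output curve at its threshold
#' `u = K`: `rho * n / (4 * gamma * K)`. For a waveform-shaping cascade the
#' gain at the operating point should exceed (normalised) 1 so that
#' deviations from the threshold are amplified stage to stage; stages whose
#' gain is at or below 1 are reported with a warning by
#' [check_gain_condition()], not rejected.
#'
#' @inheritParams buffer_steady_state
#' @return The dimensionless gain.
#' @export
buffer_gain <- function(kin, hill) {
  stopifnot(inherits(kin, "gate_kinetics"), inherits(hill, "hill_input"))
  kin$rho * hill$n / (4 * kin$gamma * hill$K)
}
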