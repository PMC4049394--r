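#' Build a three-gene repressilator circuit
#'
#' Constructs the classic ring oscillator in which each gene's protein
#' represses the next gene's transcription (`p_lacI -| p_tetR -| p_cI -|
#' p_lacI`). Each gene follows NOT-gate kinetics
#' `dp/dt = rho * f_NOT(p_prev; K, n) - gamma * p`, scaled by the regulation
#' coefficient `chi`.
#'
#' The placement of `chi` is configurable:
#' \describe{
#'   \item{`"whole"` (default)}{`chi` multiplies the entire right-hand side,
#'     a pure rescaling of time: halving `chi` exactly doubles the period
#'     while leaving the waveform (amplitude, base level) unchanged. With the
#'     default rates this calibrates to a basal period of 32 s at
#'     `chi = 0.5`.}
#'   \item{`"synthesis"`}{`chi` multiplies only the synthesis term. This
#'     changes the nullclines themselves; with the default rates the
#'     oscillation dies below `chi` of roughly 0.8, so it cannot reproduce
#'     the 32 s calibration point and is provided for comparison only.}
#' }
#'
#' @param chi Regulation coefficient, > 0.
#' @param synthesis Protein synthesis rate of each gene.
#' @param decay Protein decay rate of each gene.
#' @param hill [hill_input()] shared by the three repression terms.
#' @param initials Numeric length-3 vector of initial concentrations for
#'   (`p_lacI`, `p_tetR`, `p_cI`).
#' @param chi_scaling `"whole"` or `"synthesis"` (see Details).
#' @param names Species names, in the order lacI, tetR, cI.
#' @return A [circuit_spec()] with three NOT gates.
#' @examples
#' osc <- build_repressilator(chi = 0.5)
#' @export
build_repressilator <- function(chi = 0.5,
                                synthesis = 0.6851,
                                decay = 0.233,
                                hill = hill_input(1, 4),
                                initials = c(0.7, 1.2, 1.7),
                                chi_scaling = c("whole", "synthesis"),
                                names = c("p_lacI", "p_tetR", "p_cI")) {
  if (!is.finite(chi) || chi <= 0) {
    .gc_stop("regulation coefficient chi must be > 0", "geneclock_domain_error")
  }
  chi_scaling <- match.arg(chi_scaling)
  stopifnot(length(initials) == 3L, length(names) == 3L)
  kin <- if (chi_scaling == "whole") {
    gate_kinetics(rho = chi * synthesis, gamma = chi * decay)
  } else {
    gate_kinetics(rho = chi * synthesis, gamma = decay)
  }
  # gene i is repressed by gene i-1 in the ring: lacI <- cI, tetR <- lacI, cI <- tetR
  repressor <- c(names[3], names[1], names[2])
  gates <- lapply(1:3, function(i) {
    gate_node(names[i], "NOT", kin,
              list(regulator(repressor[i], hill$K, hill$n)))
  })
  circuit_spec(species = data.frame(name = names, initial = initials),
               gates = gates)
}
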