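#' Parameters shared by the genes of a genetic JK flip-flop
#'
#' Every gene of a flip-flop (W, V, R, S, Q, Qb) uses the same kinetics and
#' the same operator-site Hill parameters by default, matching the reference
#' counter circuits (unit synthesis and decay rates, no basal production,
#' `K = 0.5`, `n = 4`).
#'
#' @param kinetics A [gate_kinetics()].
#' @param hill A [hill_input()] used for every operator site.
#' @return A `flip_flop_params` object.
#' @export
flip_flop_params <- function(kinetics = gate_kinetics(1, 1, 0),
                             hill = hill_input(0.5, 4)) {
  stopifnot(inherits(kinetics, "gate_kinetics"), inherits(hill, "hill_input"))
  structure(list(kinetics = kinetics, hill = hill), class = "flip_flop_params")
}

# Internal constructor shared by both edge variants. `j`, `k`, `clk` are
# signal names (resolved inside the circuit or declared as free inputs).
# Initial state: Q = 0, Qb at its maximal level rho/gamma - a consistent
# latched "0" state; everything else starts at 0.
.build_jk <- function(params, j, k, clk, prefix, edge) {
  kin <- params$kinetics
  K <- params$hill$K
  n <- params$hill$n
  nm <- function(g) paste0(prefix, ".", g)
  gk <- if (edge == "rising") c(gate = "AND", latch = "NOR") else c(gate = "NAND", latch = "NAND")
  reg <- function(src) regulator(src, K, n)
  gates <- list(
    gate_node(nm("W"), gk[["gate"]], kin, list(reg(k), reg(clk))),
    gate_node(nm("V"), gk[["gate"]], kin, list(reg(j), reg(clk))),
    gate_node(nm("R"), gk[["gate"]], kin, list(reg(nm("W")), reg(nm("Q")))),
    gate_node(nm("S"), gk[["gate"]], kin, list(reg(nm("V")), reg(nm("Qb")))),
    if (edge == "rising") {
      gate_node(nm("Q"), "NOR", kin, list(reg(nm("R")), reg(nm("Qb"))))
    } else {
      gate_node(nm("Q"), "NAND", kin, list(reg(nm("S")), reg(nm("Qb"))))
    },
    if (edge == "rising") {
      gate_node(nm("Qb"), "NOR", kin, list(reg(nm("S")), reg(nm("Q"))))
    } else {
      gate_node(nm("Qb"), "NAND", kin, list(reg(nm("R")), reg(nm("Q"))))
    }
  )
  species <- data.frame(
    name = vapply(c("W", "V", "R", "S", "Q", "Qb"), nm, character(1)),
    initial = c(0, 0, 0, 0, 0, kin$rho / kin$gamma))
  internal <- species$name
  ext <- setdiff(c(j, k, clk), internal)
  circuit_spec(species = species, gates = gates, inputs = ext)
}

#' Rising edge-triggered genetic JK flip-flop
#'
#' Six genes: `W = AND(K, CLK)`, `V = AND(J, CLK)`, `R = AND(W, Q)`,
#' `S = AND(V, Qb)`, and a cross-coupled NOR latch `Q = NOR(R, Qb)`,
#' `Qb = NOR(S, Q)`. Driven by a narrow clock pulse (low most of the cycle),
#' the latch samples J and K during the pulse: with constant logic inputs it
#' realises the full JK table (hold / reset / set / toggle for J,K =
#' 0,0 / 0,1 / 1,0 / 1,1) once per low-to-high clock transition.
#'
#' @param params A [flip_flop_params()].
#' @param j_src,k_src Signal names for the J and K inputs, or numbers (a
#'   constant source `<prefix>.J` / `<prefix>.K` is then created).
#' @param clk_src Signal name of the clock pulse.
#' @param prefix Prefix for the six species names (`<prefix>.W`, ...,
#'   `<prefix>.Qb`).
#' @return A [circuit_spec()]; unresolved input names are declared as free
#'   inputs to be bound with [cascade()] or [add_drive()].
#' @export
build_jk_rising <- function(params = flip_flop_params(), j_src, k_src, clk_src,
                            prefix = "ff") {
  .build_jk_external(params, j_src, k_src, clk_src, prefix, "rising")
}

#' Falling edge-triggered genetic JK flip-flop
#'
#' Six NAND genes: `W = NAND(K, CLK)`, `V = NAND(J, CLK)`, `R = NAND(W, Q)`,
#' `S = NAND(V, Qb)`, latch `Q = NAND(S, Qb)`, `Qb = NAND(R, Q)`. Driven by
#' a wide clock (high most of the cycle, short low window), the latch
#' becomes transparent during the low window, so with `J = K = 1` the state
#' toggles once per high-to-low transition. Note that this printed NAND
#' topology is only a faithful JK element in toggle mode: for J or K held
#' low the network is not a latch (see the package vignette), which is how
#' it behaves here as well.
#'
#' @inheritParams build_jk_rising
#' @return A [circuit_spec()].
#' @export
build_jk_falling <- function(params = flip_flop_params(), j_src, k_src, clk_src,
                             prefix = "ff") {
  .build_jk_external(params, j_src, k_src, clk_src, prefix, "falling")
}

.build_jk_external <- function(params, j_src, k_src, clk_src, prefix, edge) {
  stopifnot(inherits(params, "flip_flop_params"))
  src <- list()
  fix <- function(x, slot) {
    if (is.numeric(x)) {
      nmx <- paste0(prefix, ".", slot)
      src[[nmx]] <<- as.numeric(x)
      nmx
    } else {
      .gc_check_name(x, paste(slot, "source"))
    }
  }
  j <- fix(j_src, "J"); k <- fix(k_src, "K")
  .gc_check_name(clk_src, "clock source")
  circ <- .build_jk(params, j, k, clk_src, prefix, edge)
  if (length(src)) {
    circ$sources <- c(circ$sources, unlist(src))
    circ$inputs <- setdiff(circ$inputs, names(src))
  }
  circ
}

#' Synchronous binary (2^delta-fold) genetic counter
#'
#' Chains `delta` rising edge-triggered JK flip-flops on one clock pulse.
#' The first flip-flop's J and K are tied to logic 1 (constant source
#' `one`), so its output `ff1.Q` toggles every pulse and oscillates at twice
#' the clock period; `ff2` is fed by `ff1.Q`, and stages three onward by
#' carry AND genes `G1..G(delta-2)` (`Gm` computes AND of the previous
#' stage's J/K signal and its Q), giving output periods of `2^m` clock
#' periods at stage `m`.
#'
#' @param delta Number of flip-flops, >= 1.
#' @param params A [flip_flop_params()] used for every gene, carry genes
#'   included.
#' @param clk_src Name of the clock-pulse signal (free input unless a drive
#'   or species of that name is supplied by composition).
#' @param logic_one Level of the logic-1 constant source.
#' @return A [circuit_spec()] with flip-flops `ff1..ff<delta>` and carry
#'   genes `G1..G(delta-2)`.
#' @export
build_binary_counter <- function(delta, params = flip_flop_params(),
                                 clk_src = "clk", logic_one = 1.0) {
  if (!is.numeric(delta) || delta < 1 || delta != round(delta)) {
    .gc_stop("delta must be a positive integer", "geneclock_domain_error")
  }
  delta <- as.integer(delta)
  jk_sig <- character(delta)
  jk_sig[1] <- "one"
  if (delta >= 2) jk_sig[2] <- "ff1.Q"
  if (delta >= 3) jk_sig[3:delta] <- paste0("G", seq_len(delta - 2L))
  circ <- NULL
  for (m in seq_len(delta)) {
    ff <- .build_jk(params, jk_sig[m], jk_sig[m], clk_src, paste0("ff", m), "rising")
    circ <- if (is.null(circ)) ff else cascade(circ, ff)
  }
  if (delta >= 3) {
    K <- params$hill$K; n <- params$hill$n
    carries <- lapply(seq_len(delta - 2L), function(m) {
      gate_node(paste0("G", m), "AND", params$kinetics,
                list(regulator(jk_sig[m + 1L], K, n),
                     regulator(paste0("ff", m + 1L, ".Q"), K, n)))
    })
    carry_circ <- circuit_spec(
      species = data.frame(name = paste0("G", seq_len(delta - 2L)), initial = 0),
      gates = carries,
      inputs = unique(c(jk_sig[2:(delta - 1L)],
                        paste0("ff", 2:(delta - 1L), ".Q"))))
    circ <- cascade(circ, carry_circ)
  }
  circ$sources <- c(circ$sources, c(one = logic_one))
  circ$inputs <- unique(c(setdiff(circ$inputs, "one"), clk_src))
  circ
}

#' Synchronous modulo-3 genetic counter
#'
#' Two rising edge-triggered flip-flops clocked by a narrow (low-to-high)
#' pulse and one falling edge-triggered flip-flop clocked by a wide
#' (high-to-low) pulse, wired `K1 = K2 = 1`, `J1 = ff2.Qb`, `J2 = ff1.Q`,
#' `J3 = ff2.Q`, `K3 = ff2.Qb`, with an output gene
#' `G1 = OR(ff2.Q, ff3.Q)` intended to complete one cycle every three clock
#' cycles.
#'
#' @param params A [flip_flop_params()] for every gene.
#' @param clk_rise_src Name of the low-to-high clock pulse signal.
#' @param clk_fall_src Name of the high-to-low clock pulse signal.
#' @param logic_one Level of the logic-1 constant source.
#' @return A [circuit_spec()] with 18 flip-flop species, the `G1` output
#'   gene, and the two clock names as free inputs.
#' @export
build_mod3_counter <- function(params = flip_flop_params(),
                               clk_rise_src = "clk_rise",
                               clk_fall_src = "clk_fall",
                               logic_one = 1.0) {
  if (identical(clk_rise_src, clk_fall_src)) {
    .gc_stop("the rising and falling clock pulses must be distinct signals",
             "geneclock_wiring_error")
  }
  ff1 <- .build_jk(params, "ff2.Qb", "one", clk_rise_src, "ff1", "rising")
  ff2 <- .build_jk(params, "ff1.Q", "one", clk_rise_src, "ff2", "rising")
  ff3 <- .build_jk(params, "ff2.Q", "ff2.Qb", clk_fall_src, "ff3", "falling")
  circ <- cascade(cascade(ff1, ff2), ff3)
  K <- params$hill$K; n <- params$hill$n
  out <- circuit_spec(
    species = data.frame(name = "G1", initial = 0),
    gates = list(gate_node("G1", "OR", params$kinetics,
                           list(regulator("ff2.Q", K, n),
                                regulator("ff3.Q", K, n)))))
  circ <- cascade(circ, out)
  circ$sources <- c(circ$sources, c(one = logic_one))
  circ$inputs <- c(clk_rise_src, clk_fall_src)
  circ
}
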