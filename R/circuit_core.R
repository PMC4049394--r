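#' Regulator wiring entry
#'
#' Binds a signal name (a species, constant source, drive, or declared input
#' of the circuit) to a promoter operator site with its own Hill parameters.
#'
#' @param source Name of the regulating signal.
#' @param K,n Hill constant and coefficient of this operator site.
#' @return A `regulator` object.
#' @export
regulator <- function(source, K, n) {
  .gc_check_name(source, "regulator source")
  structure(list(source = source, hill = hill_input(K, n)), class = "regulator")
}

#' Gate node: one gene in a circuit
#'
#' A gate node produces one protein species whose synthesis is controlled by
#' a promoter activity function of the regulators' concentrations:
#' `dp/dt = rho * f_kind(u) - gamma * p + rho0`.
#'
#' @param output Name of the species this gene produces.
#' @param kind Gate kind (see [gate_arity()]).
#' @param kinetics A [gate_kinetics()] object.
#' @param regulators List of [regulator()] entries; length must match the
#'   gate kind's arity.
#' @return A `gate_node` object.
#' @export
gate_node <- function(output, kind, kinetics, regulators) {
  .gc_check_name(output, "gate output")
  kind <- match.arg(toupper(kind), GATE_KINDS)
  stopifnot(inherits(kinetics, "gate_kinetics"))
  if (!is.list(regulators) || !all(vapply(regulators, inherits, logical(1), "regulator"))) {
    .gc_stop("regulators must be a list of regulator() entries", "geneclock_domain_error")
  }
  if (length(regulators) != gate_arity(kind)) {
    .gc_stop(sprintf("gate %s (kind %s) takes %d regulator(s), got %d",
                     output, kind, gate_arity(kind), length(regulators)),
             "geneclock_arity_error")
  }
  structure(list(output = output, kind = kind, kinetics = kinetics,
                 regulators = regulators),
            class = "gate_node")
}

#' Circuit specification (netlist)
#'
#' A named collection of dynamic species (each produced by exactly one gate),
#' constant sources (fixed concentrations, e.g. logic-1 inputs), external
#' drives (known functions of time, see [square_drive()]), and declared free
#' inputs to be bound later with [cascade()].
#'
#' @param species `data.frame` with columns `name` and `initial`
#'   (initial concentration, >= 0).
#' @param gates List of [gate_node()] objects, one per species.
#' @param sources Named numeric vector of constant concentration sources.
#' @param drives Named list of drive objects (class `circuit_drive`).
#' @param inputs Character vector of free input names.
#' @return A `circuit_spec` object.
#' @seealso [validate_circuit()], [compile_rhs()], [simulate_circuit()]
#' @export
circuit_spec <- function(species, gates, sources = numeric(), drives = list(),
                         inputs = character()) {
  stopifnot(is.data.frame(species), all(c("name", "initial") %in% names(species)))
  species <- data.frame(name = as.character(species$name),
                        initial = as.numeric(species$initial),
                        stringsAsFactors = FALSE)
  obj <- structure(list(species = species, gates = gates,
                        sources = sources, drives = drives,
                        inputs = unique(as.character(inputs))),
                   class = "circuit_spec")
  obj
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %d species, %d gates, %d sources, %d drives",
              nrow(x$species), length(x$gates), length(x$sources),
              length(x$drives)))
  if (length(x$inputs)) cat(", free inputs:", paste(x$inputs, collapse = ", "))
  cat("\n")
  invisible(x)
}

# every name visible as a regulator source
.all_names <- function(circuit) {
  c(circuit$species$name, names(circuit$sources), names(circuit$drives),
    circuit$inputs)
}

#' Validate a circuit specification
#'
#' Checks structural invariants: unique names, exactly one producing gate per
#' species, resolvable regulator references, matching gate arity, and
#' non-negative initial concentrations. Returns diagnostics instead of
#' raising errors, so a partially built circuit can be inspected.
#'
#' @param circuit A [circuit_spec()].
#' @return A character vector of diagnostics; empty if the circuit is valid.
#' @export
validate_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_spec"))
  diag <- character()
  nm <- .all_names(circuit)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    diag <- c(diag, sprintf("duplicate name: %s", dup))
  }
  if (any(circuit$species$initial < 0)) {
    bad <- circuit$species$name[circuit$species$initial < 0]
    diag <- c(diag, sprintf("negative initial concentration for species %s", bad))
  }
  outs <- vapply(circuit$gates, `[[`, character(1), "output")
  dup_prod <- unique(outs[duplicated(outs)])
  if (length(dup_prod)) {
    diag <- c(diag, sprintf("duplicate producer for species %s", dup_prod))
  }
  orphan <- setdiff(outs, circuit$species$name)
  if (length(orphan)) {
    diag <- c(diag, sprintf("gate output %s is not a declared species", orphan))
  }
  unproduced <- setdiff(circuit$species$name, outs)
  if (length(unproduced)) {
    diag <- c(diag, sprintf("species %s has no producing gate", unproduced))
  }
  for (g in circuit$gates) {
    if (length(g$regulators) != gate_arity(g$kind)) {
      diag <- c(diag, sprintf("gate %s: kind %s takes %d regulator(s), got %d",
                              g$output, g$kind, gate_arity(g$kind),
                              length(g$regulators)))
    }
    for (r in g$regulators) {
      if (!(r$source %in% nm)) {
        diag <- c(diag, sprintf("gate %s references unknown signal %s",
                                g$output, r$source))
      }
    }
  }
  diag
}

#' Compose two circuits, binding downstream inputs to upstream signals
#'
#' Merges an upstream and a downstream circuit into one netlist. Free inputs
#' of the downstream circuit named in `wiring` are bound to upstream species
#' or sources; regulator references are rewritten accordingly. Name
#' collisions are errors (prefix the builders' species names to avoid them).
#' When the downstream circuit does not feed back into the upstream one, the
#' upstream dynamics are unchanged by composition.
#'
#' @param upstream,downstream [circuit_spec()] objects.
#' @param wiring Named character vector: `c(<downstream input> = <upstream
#'   species or source>)`.
#' @return The merged [circuit_spec()].
#' @export
cascade <- function(upstream, downstream, wiring = character()) {
  stopifnot(inherits(upstream, "circuit_spec"), inherits(downstream, "circuit_spec"))
  solid <- function(x) c(x$species$name, names(x$sources), names(x$drives))
  clash <- intersect(solid(upstream), solid(downstream))
  if (length(clash)) {
    .gc_stop(paste("name collision between circuits:", paste(clash, collapse = ", ")),
             "geneclock_naming_error")
  }
  wiring <- vapply(wiring, as.character, character(1))
  if (length(wiring)) {
    if (!all(names(wiring) %in% downstream$inputs)) {
      bad <- setdiff(names(wiring), downstream$inputs)
      .gc_stop(paste("wiring names are not free inputs of the downstream circuit:",
                     paste(bad, collapse = ", ")), "geneclock_wiring_error")
    }
    tgt_ok <- wiring %in% solid(upstream)
    if (!all(tgt_ok)) {
      .gc_stop(paste("wiring targets do not exist upstream:",
                     paste(wiring[!tgt_ok], collapse = ", ")),
               "geneclock_wiring_error")
    }
  }
  gates <- downstream$gates
  if (length(wiring)) {
    gates <- lapply(gates, function(g) {
      g$regulators <- lapply(g$regulators, function(r) {
        if (r$source %in% names(wiring)) r$source <- unname(wiring[[r$source]])
        r
      })
      g
    })
  }
  merged <- circuit_spec(
    species = rbind(upstream$species, downstream$species),
    gates = c(upstream$gates, gates),
    sources = c(upstream$sources, downstream$sources),
    drives = c(upstream$drives, downstream$drives),
    inputs = c(upstream$inputs, setdiff(downstream$inputs, names(wiring)))
  )
  # free inputs of one side naming species/sources of the other are thereby bound
  merged$inputs <- setdiff(merged$inputs, solid(merged))
  merged
}

#' Compile a circuit into an ODE vector field
#'
#' Resolves the netlist into a pure derivative function suitable for
#' [deSolve::ode()]. The state vector follows species declaration order.
#' Regulator levels are clamped at zero before Hill evaluation so that tiny
#' negative solver undershoots cannot produce NaN for fractional Hill
#' coefficients; the linear decay term uses the raw state.
#'
#' @param circuit A valid [circuit_spec()] with no unbound inputs referenced
#'   by any gate.
#' @return A list with elements `fun` (a `function(t, y, parms)` returning
#'   `list(dy)`), `species` (state ordering), and `drives` (drive names).
#' @export
compile_rhs <- function(circuit) {
  diag <- validate_circuit(circuit)
  if (length(diag)) {
    .gc_stop(paste0("invalid circuit:\n  ", paste(diag, collapse = "\n  ")),
             "geneclock_wiring_error")
  }
  used <- unique(unlist(lapply(circuit$gates, function(g)
    vapply(g$regulators, `[[`, character(1), "source"))))
  free <- intersect(used, circuit$inputs)
  if (length(free)) {
    .gc_stop(paste("circuit has unbound inputs:", paste(free, collapse = ", "),
                   "- bind them with cascade() or add a drive of that name"),
             "geneclock_wiring_error")
  }

  sp <- circuit$species$name
  ns <- length(sp)
  gates <- circuit$gates[match(sp, vapply(circuit$gates, `[[`, character(1), "output"))]
  kindv <- vapply(gates, `[[`, character(1), "kind")
  rho   <- vapply(gates, function(g) g$kinetics$rho, numeric(1))
  gam   <- vapply(gates, function(g) g$kinetics$gamma, numeric(1))
  rho0  <- vapply(gates, function(g) g$kinetics$rho0, numeric(1))

  drv_names <- names(circuit$drives)
  drv_funs <- lapply(circuit$drives, function(d) d$fun)

  # regulator resolution tables: type 1 = species, 2 = source, 3 = drive
  resolve <- function(src) {
    i <- match(src, sp)
    if (!is.na(i)) return(c(1L, i, NA_real_))
    if (src %in% names(circuit$sources)) {
      return(c(2L, NA_integer_, unname(circuit$sources[[src]])))
    }
    c(3L, match(src, drv_names), NA_real_)
  }
  reg_tab <- function(slot) {
    typ <- integer(ns); idx <- integer(ns)
    val <- numeric(ns); K <- rep(NA_real_, ns); n <- rep(NA_real_, ns)
    for (i in seq_len(ns)) {
      regs <- gates[[i]]$regulators
      if (length(regs) < slot) next
      r <- regs[[slot]]
      rr <- resolve(r$source)
      typ[i] <- rr[1]; idx[i] <- rr[2]; val[i] <- rr[3]
      K[i] <- r$hill$K; n[i] <- r$hill$n
    }
    list(typ = typ, idx = idx, val = val, K = K, n = n)
  }
  r1 <- reg_tab(1L)
  r2 <- reg_tab(2L)

  one_in <- kindv %in% c("NOT", "BUFFER")
  i_not <- which(kindv == "NOT");  i_buf <- which(kindv == "BUFFER")
  i_and <- which(kindv == "AND");  i_or  <- which(kindv == "OR")
  i_xor <- which(kindv == "XOR");  i_nan <- which(kindv == "NAND")
  i_nor <- which(kindv == "NOR")
  two <- which(!one_in)

  lvl <- function(tab, t, yc, dv) {
    u <- numeric(ns)
    isp <- tab$typ == 1L
    u[isp] <- yc[tab$idx[isp]]
    isr <- tab$typ == 2L
    u[isr] <- tab$val[isr]
    idr <- tab$typ == 3L
    if (any(idr)) u[idr] <- dv[tab$idx[idr]]
    u
  }

  fun <- function(t, y, parms) {
    yc <- pmax(y, 0)
    dv <- if (length(drv_funs)) {
      vapply(drv_funs, function(f) f(t), numeric(1))
    } else numeric()
    u1 <- lvl(r1, t, yc, dv)
    x1 <- numeric(ns)
    p1 <- u1 > 0
    x1[p1] <- (u1[p1] / r1$K[p1])^r1$n[p1]
    f <- numeric(ns)
    if (length(i_not)) f[i_not] <- 1 / (1 + x1[i_not])
    if (length(i_buf)) f[i_buf] <- x1[i_buf] / (1 + x1[i_buf])
    if (length(two)) {
      u2 <- lvl(r2, t, yc, dv)
      x2 <- numeric(ns)
      p2 <- u2 > 0
      x2[p2] <- (u2[p2] / r2$K[p2])^r2$n[p2]
      z <- 1 + x1[two] + x2[two] + x1[two] * x2[two]
      fz <- numeric(ns)
      fz[two] <- z
      if (length(i_and)) f[i_and] <- x1[i_and] * x2[i_and] / fz[i_and]
      if (length(i_or))  f[i_or]  <- (x1[i_or] + x2[i_or] + x1[i_or] * x2[i_or]) / fz[i_or]
      if (length(i_xor)) f[i_xor] <- (x1[i_xor] + x2[i_xor]) / fz[i_xor]
      if (length(i_nan)) f[i_nan] <- (1 + x1[i_nan] + x2[i_nan]) / fz[i_nan]
      if (length(i_nor)) f[i_nor] <- 1 / fz[i_nor]
    }
    list(rho * f - gam * y + rho0)
  }

  list(fun = fun, species = sp, drives = drv_names)
}
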