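CIRCUIT_FORMAT_VERSION <- 1L

#' Write a circuit document
#'
#' Serialises a [circuit_spec()] to a human-editable YAML document with an
#' explicit `format_version`. Constant sources, square-wave drives and free
#' inputs round-trip losslessly; drives of other types (arbitrary R
#' functions) cannot be serialised and raise an error.
#'
#' @param circuit A [circuit_spec()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path) {
  stopifnot(inherits(circuit, "circuit_spec"))
  doc <- list(
    format_version = CIRCUIT_FORMAT_VERSION,
    species = lapply(seq_len(nrow(circuit$species)), function(i) {
      list(name = circuit$species$name[i], initial = circuit$species$initial[i])
    }),
    gates = lapply(circuit$gates, function(g) {
      list(output = g$output, kind = g$kind,
           rho = g$kinetics$rho, gamma = g$kinetics$gamma, rho0 = g$kinetics$rho0,
           regulators = lapply(g$regulators, function(r) {
             list(source = r$source, K = r$hill$K, n = r$hill$n)
           }))
    })
  )
  if (length(circuit$sources)) doc$sources <- as.list(circuit$sources)
  if (length(circuit$drives)) {
    doc$drives <- lapply(circuit$drives, function(d) {
      if (!identical(d$type, "square")) {
        .gc_stop(paste("cannot serialise drive of type", d$type),
                 "geneclock_schema_error")
      }
      c(list(type = "square"), d$pars)
    })
  }
  if (length(circuit$inputs)) doc$inputs <- as.list(circuit$inputs)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a circuit document
#'
#' Parses a YAML circuit document written by [write_circuit()] (or by
#' hand), validates it, and reports diagnostics as warnings. A species entry
#' without an `initial` value defaults to 0 with a warning; an unknown gate
#' kind is a schema error.
#'
#' @param path File path to read.
#' @return A [circuit_spec()].
#' @export
read_circuit <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    .gc_stop(paste0("cannot parse circuit document ", path, ": ",
                    conditionMessage(e)), "geneclock_parse_error")
  })
  ver <- doc$format_version
  if (is.null(ver) || !ver %in% CIRCUIT_FORMAT_VERSION) {
    .gc_stop(paste("unsupported or missing format_version in", path),
             "geneclock_schema_error")
  }
  sp <- do.call(rbind, lapply(doc$species, function(s) {
    if (is.null(s$name)) .gc_stop("species entry without a name", "geneclock_schema_error")
    init <- s$initial
    if (is.null(init)) {
      warning(sprintf("species %s has no initial concentration; defaulting to 0",
                      s$name), call. = FALSE)
      init <- 0
    }
    data.frame(name = s$name, initial = as.numeric(init))
  }))
  gates <- lapply(doc$gates, function(g) {
    kind <- toupper(as.character(g$kind))
    if (!kind %in% GATE_KINDS) {
      .gc_stop(sprintf("unknown gate kind '%s' for gate %s (supported: %s)",
                       g$kind, g$output, paste(GATE_KINDS, collapse = ", ")),
               "geneclock_schema_error")
    }
    gate_node(g$output, kind,
              gate_kinetics(g$rho, g$gamma, if (is.null(g$rho0)) 0 else g$rho0),
              lapply(g$regulators, function(r) {
                # hand-written YAML may leave the n key unquoted, which the
                # parser resolves as the boolean FALSE
                regulator(r$source, r$K, r$n %||% r[["FALSE"]])
              }))
  })
  sources <- if (is.null(doc$sources)) numeric() else unlist(doc$sources)
  drives <- list()
  for (dn in names(doc$drives)) {
    d <- doc$drives[[dn]]
    if (!identical(d$type, "square")) {
      .gc_stop(paste("unknown drive type:", d$type), "geneclock_schema_error")
    }
    drives[[dn]] <- square_drive(period = d$period, duty = d$duty,
                                 high = d$high, low = d$low,
                                 t_rise = d$t_rise, phase = d$phase)
  }
  circ <- circuit_spec(species = sp, gates = gates, sources = sources,
                       drives = drives,
                       inputs = unlist(doc$inputs %||% character()))
  diag <- validate_circuit(circ)
  if (length(diag)) {
    warning(paste0("circuit document ", path, " has issues:\n  ",
                   paste(diag, collapse = "\n  ")), call. = FALSE)
  }
  circ
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace as CSV
#'
#' Header `time,<signal...>`; values keep 15 significant digits so metric
#' results are reproduced at the reported precision after a round trip.
#'
#' @param trace A `circuit_trace`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "circuit_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace CSV
#'
#' @param path File path of a CSV written by [write_trace()].
#' @return A `circuit_trace`.
#' @export
read_trace <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) {
                   .gc_stop(paste0("cannot parse trace CSV ", path, ": ",
                                   conditionMessage(e)), "geneclock_parse_error")
                 })
  if (nrow(df) == 0L) df[] <- lapply(df, as.numeric)
  if (!"time" %in% names(df) || !all(vapply(df, is.numeric, logical(1)))) {
    .gc_stop(paste("malformed trace CSV:", path), "geneclock_parse_error")
  }
  as_circuit_trace(df)
}
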