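# --- expression -> MathML --------------------------------------------------

.mathml <- function(e) {
  if (is.numeric(e)) {
    return(sprintf("<cn type=\"real\"> %.15g </cn>", e))
  }
  if (is.name(e)) {
    return(sprintf("<ci> %s </ci>", as.character(e)))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.mathml(e[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", NULL)
    if (is.null(tag)) stop("unsupported operator in rate law: ", op)
    args <- vapply(as.list(e)[-1], .mathml, character(1))
    return(paste0("<apply> <", tag, "/> ", paste(args, collapse = " "),
                  " </apply>"))
  }
  stop("unsupported rate-law term of class ", class(e)[1])
}

# occupancy term (u/K)^n as an unevaluated call
.occ_expr <- function(reg) {
  substitute((u / K)^n, list(u = as.name(reg$source),
                             K = reg$hill$K, n = reg$hill$n))
}

.activity_expr <- function(gate) {
  x1 <- .occ_expr(gate$regulators[[1]])
  if (gate$kind %in% c("NOT", "BUFFER")) {
    return(switch(gate$kind,
      NOT    = substitute(1 / (1 + x1), list(x1 = x1)),
      BUFFER = substitute(x1 / (1 + x1), list(x1 = x1))))
  }
  x2 <- .occ_expr(gate$regulators[[2]])
  z <- substitute(1 + x1 + x2 + x1 * x2, list(x1 = x1, x2 = x2))
  switch(gate$kind,
    AND  = substitute((x1 * x2) / z, list(x1 = x1, x2 = x2, z = z)),
    OR   = substitute((x1 + x2 + x1 * x2) / z, list(x1 = x1, x2 = x2, z = z)),
    XOR  = substitute((x1 + x2) / z, list(x1 = x1, x2 = x2, z = z)),
    NAND = substitute((1 + x1 + x2) / z, list(x1 = x1, x2 = x2, z = z)),
    NOR  = substitute(1 / z, list(z = z)))
}

.rate_expr <- function(gate) {
  f <- .activity_expr(gate)
  k <- gate$kinetics
  e <- substitute(rho * f - gamma * p,
                  list(rho = k$rho, f = f, gamma = k$gamma,
                       p = as.name(gate$output)))
  if (k$rho0 != 0) e <- substitute(a + b, list(a = e, b = k$rho0))
  e
}

#' Export a circuit as an SBML Level 3 model
#'
#' Writes one SBML species per circuit species and one rate rule per
#' species whose MathML equals the compiled right-hand side
#' (`rho * f - gamma * p + rho0`). Constant sources become constant SBML
#' parameters. External drives (arbitrary time signals) are not expressible
#' as rate rules and raise an export error naming the drive; bind or remove
#' them first.
#'
#' @param circuit A valid [circuit_spec()] without drives or free inputs.
#' @param path Optional file path; when given the document is also written
#'   there.
#' @return An [xml2::xml_document] with the SBML model.
#' @export
export_sbml <- function(circuit, path = NULL) {
  stopifnot(inherits(circuit, "circuit_spec"))
  if (length(circuit$drives)) {
    .gc_stop(paste("cannot export circuits with external drives:",
                   paste(names(circuit$drives), collapse = ", ")),
             "geneclock_export_error")
  }
  if (length(circuit$inputs)) {
    .gc_stop(paste("cannot export circuits with unbound inputs:",
                   paste(circuit$inputs, collapse = ", ")),
             "geneclock_export_error")
  }
  diag <- validate_circuit(circuit)
  if (length(diag)) {
    .gc_stop(paste0("invalid circuit:\n  ", paste(diag, collapse = "\n  ")),
             "geneclock_export_error")
  }
  sp <- vapply(seq_len(nrow(circuit$species)), function(i) {
    sprintf(paste0("<species id=\"%s\" compartment=\"cell\" ",
                   "initialConcentration=\"%.15g\" ",
                   "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
                   "constant=\"false\"/>"),
            circuit$species$name[i], circuit$species$initial[i])
  }, character(1))
  pars <- vapply(names(circuit$sources), function(nm) {
    sprintf("<parameter id=\"%s\" value=\"%.15g\" constant=\"true\"/>",
            nm, circuit$sources[[nm]])
  }, character(1))
  rules <- vapply(circuit$gates, function(g) {
    sprintf(paste0("<rateRule variable=\"%s\"><math xmlns=\"http://www.w3.org/1998/Math/MathML\"> ",
                   "%s </math></rateRule>"),
            g$output, .mathml(.rate_expr(g)))
  }, character(1))
  doc_txt <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" ",
    "level=\"3\" version=\"2\">\n",
    "<model id=\"geneclock_circuit\">\n",
    "<listOfCompartments>",
    "<compartment id=\"cell\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>\n",
    "<listOfSpecies>\n", paste(sp, collapse = "\n"), "\n</listOfSpecies>\n",
    if (length(pars)) {
      paste0("<listOfParameters>\n", paste(pars, collapse = "\n"),
             "\n</listOfParameters>\n")
    } else "",
    "<listOfRules>\n", paste(rules, collapse = "\n"), "\n</listOfRules>\n",
    "</model>\n</sbml>\n")
  doc <- xml2::read_xml(doc_txt)
  if (!is.null(path)) xml2::write_xml(doc, path)
  doc
}
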