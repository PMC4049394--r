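Package: geneclock
Title: Genetic Sequential Logic Circuits and Clock Pulse Generators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic simulation and design of synthetic gene circuits
    built from Hill-kinetics transcriptional logic gates. Provides promoter
    activity functions for the seven canonical gate types (NOT, Buffer, AND,
    OR, XOR, NAND, NOR), a circuit netlist model compiled to an ODE vector
    field, a three-gene repressilator clock source, design of Buffer-cascade
    waveform-shaping circuits that reshape an oscillation into pulse-width
    modulated clock signals at chosen duty cycles, and edge-triggered genetic
    JK flip-flop counters that divide the clock frequency. Includes trace
    metrics (period, amplitude, duty cycle, edge detection), YAML circuit
    documents, CSV traces, SBML Level 3 export, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
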