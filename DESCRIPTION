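Package: luxcircuit
Title: Kinetic and Logic-Circuit Models of the Bacterial luxCDABE
    Bioluminescence Cassette
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of engineered whole-cell biosensors
    built on the bacterial luxCDABE operon. Implements the forward/reverse
    metabolic reaction model of bioluminescence (reaction ODEs, steady-state
    product, effective detection threshold, signal model), split-operon logic
    gates (soft-minimum/AND via paradoxical control of the forward and
    reverse reactions, and a protein-protein interaction gate), a comparator
    with a programmable detection threshold, a delayed rise-and-decay model
    of stress-responsive promoters (recA, katG), crosstalk-by-summation, an
    incoherent feedforward loop that converts chemical identity into
    bioluminescent peak counts, Hill and power-law transfer-function fitting,
    and a plate-reader-like synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
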