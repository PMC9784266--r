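Package: mopir
Title: Exact Multi-Output Boolean Minimization for Configurational
    Causal Inference
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Configurational comparative analysis of binary case data
    with several simultaneous outcomes, as arises in multi-morbidity
    research where chronic conditions co-occur.  Aggregates cases into a
    truth table with inclusion (consistency) scores, derives the complete
    set of multi-output prime implicants by a tagged Quine-McCluskey
    procedure (with a brute-force oracle for verification), enumerates
    every irredundant system of models with Petrick's method, computes
    consistency and coverage statistics, mines minimal input tuples, and
    renders solutions as two-level logic diagrams (Graphviz DOT and SVG).
    Reads case tables from CSV and function specifications from Berkeley
    PLA files.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
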