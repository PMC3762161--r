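Package: capform
Title: Capillary Formation Dynamics in Tumor Angiogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates one-dimensional capillary formation during tumor
    angiogenesis. A reinforced-random-walk continuum model couples angiogenic
    factor, proteolytic enzyme, fibronectin and endothelial cell densities on
    the unit interval with zero-flux boundaries. The package provides the
    closed-form initial-data perturbation solutions (Fourier cosine series for
    the cell perturbation), conservative finite-difference method-of-lines
    solvers for the full nonlinear system and for the linearized transient
    problem, steady-state stability analysis, parameter presets, and a
    command-line front end with CSV/JSON export.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
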