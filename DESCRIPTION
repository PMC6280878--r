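Package: snailtrail
Title: Lattice Cellular Automaton and Continuum Models of Corneal
    Angiogenesis with Volume Exclusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating corneal angiogenesis as a stochastic
    lattice cellular automaton of migrating tip cells that deposit a
    snail-trail of stalk (endothelial) cells, with chemotaxis up a linear
    tumor angiogenic factor gradient, vacancy-gated branching, and
    tip-to-tip and tip-to-sprout anastomosis under volume exclusion.
    Provides the matched one-dimensional non-linear mean-field partial
    differential equations for the column-averaged tip and stalk cell
    densities, a linear snail-trail comparator model, ensemble and column
    averaging of automaton output, and RMSE-based bounded calibration of
    the continuum parameters against averaged automaton ensembles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
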