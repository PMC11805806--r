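Package: lvcycles
Title: Heteroclinic Cycles and Invasion Graphs for Lotka-Volterra Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing generalized Lotka-Volterra systems with
    Volterra-Lyapunov (diagonally) stable interaction matrices: constructive
    generation and numerical certification of Volterra-Lyapunov stability,
    enumeration of admissible communities with their equilibria and invasion
    rates, invasion-graph construction and elementary-cycle detection,
    frondosity and diagonal-dominance criteria that exclude heteroclinic
    cycles, numerical integration of the dynamics, and reproducible
    random-matrix experiments relating cycle prevalence to the balance of
    symmetric and antisymmetric interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
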