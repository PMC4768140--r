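Package: pyloclone
Title: Clonal Dynamics, Proliferation and Differentiation of Lgr5+ Stem
    Cells in Pyloric Gastric Glands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of lineage-tracing experiments in the
    pyloric stomach epithelium. Implements the neutral-drift model of
    clonal expansion at the gland base generalized to arbitrary initial
    clone-size distributions, extinction-probability estimation of the
    effective stem-cell number, linear birth-death models of Lgr5+ cell
    proliferation and differentiation, a two-compartment model for the
    growth of labelled Lgr5- progeny, an event-driven individual-based
    simulator of the gland base, random-walk Metropolis fitting of all
    models to longitudinal clone-count tables, and a synthetic-data
    generator emulating the statistical structure of in-vivo
    lineage-tracing cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    coda,
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
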