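Package: cyclefate
Title: Stochastic Cell-Cycle Variation and Cell-Fate Propensity Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling cell-cycle length variation and
    cell-cycle-coupled cell-fate choice in Dictyostelium discoideum and
    similar systems. Implements a Gamma-Laplace model of correlated sister
    cell-cycle lengths with moment estimators, an event-driven lineage-tree
    population simulator with division-rate and de-synchronization
    statistics, a piecewise cell-cycle-position-dependent stalk-fate
    propensity model with a two-stage least-squares fitting procedure, and
    a cell-cycle transcriptome peak-binning procedure based on median
    absolute deviation outliers with hypergeometric enrichment tests.
    Synthetic-data generators emulate tracked lineage tables, induction
    experiments and hourly time-course count matrices so that every stage
    of the pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
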