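Package: ecofitsim
Title: Individual-Based Simulation of Parasite Host Switching by Ecological
    Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based model of a parasite lineage with a
    one-dimensional quantitative phenotype under Gaussian stabilizing
    selection imposed by its host. Each generation the population
    reproduces (recombination plus mutation), is offered a single novel
    host resource, and may disperse to and colonize it; establishment on
    the new host discards the ancestral population, so runs trace a chain
    of host switches until extinction or a generation cap. The package
    provides the simulation engine, Information Space (standardized
    phenotypic amplitude) metrics, binned colonization-success curves and
    phase diagrams, Spearman partial correlation, a batch/robustness-sweep
    harness, and TSV/JSON serialization with a small command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
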