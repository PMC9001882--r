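Package: antitune
Title: Multiobjective Tuning of Antithetic Feedback Controllers for
    Dynamic Metabolic Pathway Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic models of merging metabolic pathways placed
    under dynamic feedback regulation by a biomolecular antithetic (sigma /
    anti-sigma) integral controller, including a detailed model of the
    naringenin biosynthesis pathway in Escherichia coli with an extended
    kaempferol/QdoR biosensor and an AHL/LuxR reference input.  Provides a
    perturbation-rejection simulation protocol (step reduction of the
    secondary co-substrate, e.g. malonyl-CoA), objective functions for titer
    target error, production loss after perturbation and controller
    oscillation count, and a constrained multiobjective differential-evolution
    optimizer with an external non-dominated archive and spherical pruning.
    Pareto libraries of controller-biosensor designs can be explored with
    level-diagram multicriteria decision support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
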