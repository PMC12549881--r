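Package: balcomplex
Title: Balanced Complexes, Forced Balancing and Concordance Modules in
    Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes stoichiometric metabolic models into complexes and a
    complex-reaction incidence graph (N = Y*A), detects balanced complexes and
    concordance modules by linear programming over the steady-state flux
    polytope, performs forced balancing of non-balanced complexes to compute
    balancing potentials and the trivial / non-trivial type-I / type-II
    classification of the induced balanced set, fits balancing-potential
    distributions with a discrete power law with exponential cut-off, and
    screens paired disease/healthy models for complexes whose forced balancing
    is lethal in the disease model while preserving growth in the healthy
    model.  Reads SBML (Level 3 FBC) as well as plain JSON/TSV model dialects
    and ships deterministic fixtures and generators so every stage is testable
    without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
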