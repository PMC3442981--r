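Package: budstrain
Title: Constraint-Based Design of Growth-Coupled 2,3-Butanediol Producing
    Yeast Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis, flux variability analysis, production
    envelopes, gene-protein-reaction knockout logic and bilevel knockout
    design (OptKnock, solved as a single-level MILP via LP strong duality)
    for compartmentalized constraint-based metabolic models. Ships a
    hand-solvable yeast-like fermentation network centred on the pyruvate
    branch point (ethanol / glycerol / acetoin -> 2,3-butanediol) with
    NADH/NAD and ATP/ADP cofactor coupling, a seeded random-model
    generator, and a brute-force knockout-design oracle, so every stage of
    the strain-design pipeline is testable on desk-scale models. Reads and
    writes SBML (Level 3 FBC and legacy COBRA-notes dialects) and a native
    JSON model schema; includes a command-line driver and an opt-in
    reproduction mode for the published iMM904 yeast genome-scale model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
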