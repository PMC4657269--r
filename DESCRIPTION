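Package: rcfba
Title: Resource-Constrained Flux Balance Analysis in Fluctuating Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based metabolic modelling for organisms that shuttle
    between alternative nutrient conditions. Extends flux balance analysis with
    per-environment enzyme investments drawn from a shared cellular-resource
    budget and a switching-investment penalty proportional to investment
    differences between environments, solved as a coupled multi-environment
    linear program. Includes optimal-network inference from investment support,
    switching-parameter sweeps with structural/regulatory transition detection,
    regulon counting, directed metabolite-graph construction with currency-
    metabolite removal and bow-tie structural metrics, single-reaction
    essentiality screening, and nonparametric lifestyle-group comparison of
    reconstructed models. Reads and writes SBML Level 3 FBC, COBRA JSON and a
    plain tabular reaction dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Python (>= 3.8) with scipy (HiGHS linear-programming
    backend), discoverable as 'python' or 'python3' on the PATH or via
    options(rcfba.python=...).
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'universe.R'
    'environments.R'
    'io.R'
    'fixtures.R'
    'lp-backend.R'
    'rcfba.R'
    'sweep.R'
    'metgraph.R'
    'essentiality.R'
    'compare.R'
    'pipeline.R'
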