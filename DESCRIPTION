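Package: molforge
Title: Composable Molecular Design Workflows: Generation, Filtering,
    Sparse Array Design, Free-Wilson Models and Active Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable engine for automated small-molecule design
    iterations. Generates candidate structures from lead molecules by
    matched-molecular-pair transforms and BRICS fragment replacement,
    filters them against a target compound profile (property windows and
    SMARTS liability alerts), ranks by linear desirability or Pareto
    dominance, designs equally sampled incomplete balanced block
    ("sparse") combinatorial arrays with steepest-descent reagent
    assignment, fits classical Free-Wilson additive R-group models, and
    selects explore/exploit batches with tree-ensemble active learning.
    Tasks compose into validated linear workflows; a synthetic-library
    simulator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    xml2,
    randomForest,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
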