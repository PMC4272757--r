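Package: mmpamp
Title: Prediction-Driven Matched Molecular Pair Analysis and Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies matched molecular pairs (MMPs) and molecular
    transformations in compound sets by a fragment-and-index algorithm,
    tests transformations for statistically significant effects on
    continuous and binary endpoints with exact binomial sign tests and
    Holm-Bonferroni correction, combines experimental measurements with
    QSAR predictions (including an applicability-domain-aware bootstrap)
    to "amplify" under-powered transformations, and applies the resulting
    significant transformations to target molecules in an automated
    optimization loop with Tanimoto similarity filtering and hit
    accounting. Includes a deterministic synthetic-library generator with
    planted transformation effects, transformation-graph and delta-pair
    chart exports, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
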