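Package: probkg
Title: Probabilistic Knowledge Graphs for Disease Target Identification
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds probabilistic knowledge graphs over drugs, proteins,
    diseases and side effects by fusing heterogeneous biological networks
    with literature co-occurrence evidence, learns relation-specific graph
    embeddings that reconstruct the weighted graph, and scores held-out
    target-disease associations. Includes dense sequence- and
    structure-similarity networks, dictionary-based co-occurrence counting,
    entry-wise and cluster-wise cross-validation, exposure-bias and
    literature-support diagnostics, randomized ablation controls, and a
    synthetic-data generator with planted low-rank association structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
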