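Package: sigrecon
Title: Signaling Network Reconstruction from Prior Knowledge and Boolean
    Phosphoproteomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains directed protein signaling networks against Boolean
    stimulus-by-signal phosphoproteomic measurements.  Starting from a prior
    knowledge network (PKN) of candidate reactions, the package extracts
    stimulus-to-signal dependencies from the data matrix, satisfies them
    through conflict-free shortest paths (all-pairs Floyd-Warshall with
    deterministic path reconstruction), searches alternative routes by
    breadth-first traversal, scores conflicted candidate pathways by weighing
    served dependencies against introduced inconsistencies, and nullifies
    admitted conflicts in a final rescoring pass.  The compressed topology is
    evaluated with a reachability-based percentage fit error, cross-validated
    against random data matrices with a fixed activation count, and compared
    to external edge sets with the Jaccard index.  Results can be exported as
    Graphviz DOT text, TSV reports and JSON decision logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
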