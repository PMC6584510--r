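Package: pomoc
Title: Partially Overlapping Motif Counting in Capacity-Constrained Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts network motifs in directed biological networks whose edges
    carry integer capacities, the maximum number of motif instances an
    interaction can support simultaneously. Finds a largest feasible set of
    motif embeddings by iterated local search over an embedding overlap graph
    (the POMOC measure), together with the classical F1 (unlimited overlap)
    and F2 (edge-disjoint) counts as capacity special cases, an exact
    branch-and-bound oracle for small instances, synthetic network generators
    (Erdos-Renyi, Watts-Strogatz, Barabasi-Albert), and an expression-derived
    capacity assignment for transcriptional regulatory networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
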