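Package: ppiscreen
Title: Network-Pharmacology Target Screening on Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the network-pharmacology
    screening workflow used to nominate core protein targets of a compound for
    a disease: one-hop seeded subnetwork construction on an interactome,
    network intersection, a two-stage median-threshold topological filter
    (degree "hit hubs", then a five-metric core filter using degree,
    betweenness, closeness, neighborhood connectivity and local average
    connectivity), hypergeometric over-representation analysis with
    Benjamini-Hochberg FDR control, and assembly of the tetrapartite
    compound-target-pathway-disease network. Includes a seed-controlled
    synthetic-data module (scale-free interactome with a planted dense core
    module, seed sets, and annotation term sets enriched in the core) so the
    whole screen can be exercised end-to-end against known ground truth, plus
    the two bench formulas of the accompanying experimental arm (sucrose
    preference percentage and 2^-ddCt relative expression).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
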