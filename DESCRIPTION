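Package: mechsim
Title: Graph-Based Similarity of Enzyme Reaction Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents curly-arrow diagrams of enzyme catalytic steps as
    labelled molecular graphs, extracts canonical arrow-environment subgraphs
    around the reaction centres under three configurable definitions (one-away,
    two-away, EzMechanism-like), and scores pairs of catalytic steps or whole
    mechanisms with unordered (Jaccard over arrow-environment sets) and ordered
    (mean of environment and arrow-chain Jaccard) similarities. Includes a
    documented JSON exchange format for mechanisms, a best-effort reader for a
    subset of Marvin document (.mrv) XML, SMARTS serialization of
    arrow-environments with a two-digit atom-map encoding of electron flow,
    corpus-level all-vs-all comparison, threshold clustering, chemical
    diversity statistics, and a seeded synthetic-mechanism generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
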