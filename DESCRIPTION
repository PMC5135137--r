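Package: medwordnet
Title: Time-Resolved Word Co-Occurrence Networks and Overlapping
    Community Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pointwise-mutual-information weighted word
    co-occurrence networks from time-binned document corpora (JSONL, TSV
    or PubMed/MEDLINE XML abstracts), extracts overlapping communities
    with the k-clique percolation method including data-driven selection
    of the critical clique size, computes per-interval connectivity
    statistics, and tracks community life-cycle events (growth,
    contraction, merging, splitting, appearance, disappearance) across
    consecutive time intervals. Ships a synthetic corpus generator with
    planted, evolving topic communities and exported ground truth so the
    whole pipeline can be validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
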