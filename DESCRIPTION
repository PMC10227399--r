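Package: litnet
Title: Multipartite Co-Occurrence Networks from Biomedical Full Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds undirected, weighted, multipartite co-occurrence networks
    linking genes, chemicals and therapeutic properties from full-text
    biomedical corpora. Documents are parsed from JATS/PMC-style XML or a
    line-delimited JSON corpus format, filtered for English, and scanned
    paragraph by paragraph with a dictionary-based entity tagger (with a
    plug-in seam for external taggers). Candidate entity pairs are validated
    with the Dunning log-likelihood-ratio collocation test and classified by
    co-occurrence direction; edges carry mention-count-product weights and
    paragraph-level literature provenance. A skip-gram word-embedding trainer
    supports cosine-similarity expansion of a seed lexicon of therapeutic
    properties. Subgraph querying with progressive degree filtering, heatmap
    matrices and GraphML/TSV/JSON exports support exploration, and a synthetic
    corpus generator with planted co-occurrence structure makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    xml2,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
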