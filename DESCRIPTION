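Package: lexavail
Title: Lexical Availability Graphs from Semantic Fluency Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds directed, weighted word-association graphs (lexical
    availability graphs) from semantic fluency response chains and analyses
    their structure. Provides data editing for fluency corpora, graph
    construction and weight-threshold pruning, structural metrics including a
    directed neighbourhood-density clustering coefficient, centrality
    rankings, modularity community detection with anchor-word cluster tables,
    the positional-decay lexical availability index, matched uniform random
    digraph null models for small-world testing, and a synthetic chain
    generator with planted cluster structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
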