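Package: predtopics
Title: Predicate-Pattern Topic Discovery and SPARQL Query Generation for RDF Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions the predicates of one or more RDF/OWL knowledge graphs
    into semantically coherent topics. Predicate pairs are compared through
    their neighbouring patterns (shared subject/object sets, path and cycle
    connectivity through concepts), yielding a symmetric similarity matrix that
    is clustered by a hierarchical fuzzy c-means procedure with silhouette-width
    model selection. Each resulting topic is summarised by a predicate
    signature, validated against a binary gold-standard indicator table, and
    turned into an executable SPARQL query by crawling its cluster graph in
    similarity order. A pointwise-mutual-information concept-ranking front end
    filters triples to domain-associated concepts, and a seeded synthetic
    knowledge-graph generator with planted predicate clusters supports
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
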