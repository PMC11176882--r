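Package: litgraph
Title: Graph-Query Search over Literature Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an ontology-annotated co-occurrence network from a corpus of
    publication abstracts and answers small graph queries over it by inexact
    matching. Publication metadata are cleaned and deduplicated, entity mentions
    are extracted with a deterministic dictionary matcher (pluggable NER backend)
    and linked to UMLS/CIDO-style concept lexicons, entities are curated with a
    normalized Levenshtein similarity gate, and co-occurrence edges are weighted
    by pointwise mutual information, normalized pointwise mutual information
    (NPMI), and Cramer's V, pruning edges with non-positive NPMI. Query edges
    absent from the network are expanded into minimal-hop shortest paths ranked
    by average NPMI; publications are retrieved through an inverted index and
    ranked by the number of explained relationships, NPMI sum, and publication
    date. Ships deterministic synthetic fixtures so the full pipeline is testable
    without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
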