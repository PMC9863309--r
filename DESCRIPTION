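Package: litminer
Title: Machine Reading of a Biomedical Literature Corpus: Comention
    Networks, Thematic Clustering, and Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale machine-reading pipeline for biomedical
    literature corpora. Reads a documented corpus JSON dialect, splits
    abstracts into sentences with a deterministic rule-based sentencizer,
    tags and normalizes protein and disease mentions against a synonym
    lexicon, builds sentence-level entity comention networks, clusters
    documents into themes with tf-idf vectorization and K-means (with a
    within-cluster sum-of-squares elbow diagnostic and a 2-D t-SNE
    embedding), extracts per-cluster theme keywords, and computes
    per-cluster entity and category overrepresentation with one-sided
    hypergeometric tests and Benjamini-Hochberg false discovery rates.
    Includes a synthetic-corpus generator with planted topics and planted
    entity mentions so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
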