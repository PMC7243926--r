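Package: posmrf
Title: POS-Weighted Markov Random Field Retrieval for Biomedical Dataset Metadata
Version: 0.1.0
Authors@R:
    person("posmrf", "Authors", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A retrieval engine for collections of dataset-metadata records with
    free-text title and description fields. Implements a two-field positional
    inverted index, TF-IDF, Dirichlet query-likelihood, Markov random field
    (MRF) and part-of-speech-weighted MRF ranking, query expansion with locally
    trained skip-gram word embeddings, dictionary-based medical entity
    extraction with normalization and acronym resolution, entity-overlap
    re-ranking, and evaluation with classical and statistically inferred
    measures (MAP, P@10, NDCG@10, infAP, infNDCG) against graded, possibly
    sampled, relevance judgments. A synthetic-collection generator with planted
    topical structure, synonym families and graded relevance makes the whole
    pipeline testable end-to-end without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
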