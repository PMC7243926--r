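#' Build the embedding-training token stream
#'
#' Concatenates title and description of every document into one token
#' stream, lowercased with punctuation (including hyphens) removed. Stopwords
#' are kept: the training corpus receives only the minimal normalization, and
#' the whole collection is merged into a single stream so context windows are
#' drawn corpus-wide.
#'
#' @param docs List of [dataset_doc()] objects.
#' @return Character vector of tokens in stable document order.
#' @export
build_training_corpus <- function(docs) {
  if (length(docs) == 0L) stop("cannot build a training corpus from 0 docs")
  toks <- unlist(lapply(docs, function(d) {
    c(preprocess(d$title, stoplist = NULL, split_hyphens = TRUE),
      preprocess(d$description, stoplist = NULL, split_hyphens = TRUE))
  }), use.names = FALSE)
  if (length(toks) == 0L) stop("training corpus is empty after preprocessing")
  toks
}

#' Train skip-gram word embeddings with negative sampling
#'
#' Learns one d-dimensional vector per vocabulary term by stochastic gradient
#' ascent on the negative-sampling objective
#' log sigma(w'c) + k * E\[log sigma(-w'c)\] with noise contexts drawn from the
#' unigram distribution raised to 0.75. Training is single-threaded and fully
#' determined by `seed`.
#'
#' @param corpus Token stream from [build_training_corpus()] (or a list of
#'   token vectors, which is flattened).
#' @param dim Embedding dimension (default 100).
#' @param window Maximum context window (dynamic, word2vec-style).
#' @param negative Number k of negative samples per positive pair.
#' @param epochs Passes over the stream.
#' @param min_count Minimum corpus frequency for a term to enter the
#'   vocabulary.
#' @param alpha,min_alpha Initial and floor learning rate.
#' @param seed Integer seed.
#' @return `embedding_model`: list with `vocab`, `vectors` (vocab x dim matrix
#'   with term rownames), and `meta`.
#' @export
train_embeddings <- function(corpus, dim = 100L, window = 5L, negative = 5L,
                             epochs = 5L, min_count = 1L, alpha = 0.025,
                             min_alpha = 1e-4, seed = 1L) {
  if (is.list(corpus)) corpus <- unlist(corpus, use.names = FALSE)
  if (length(corpus) == 0L) stop("empty training corpus")
  tab <- table(corpus)
  keep <- tab[tab >= min_count]
  # frequency-descending, term-ascending: a deterministic vocabulary order
  vocab <- names(keep)[order(-as.integer(keep), names(keep), method = "radix")]
  if (length(vocab) < 6L)
    stop("vocabulary has ", length(vocab),
         " terms; at least 6 are required to return 5 neighbours")
  ids <- match(corpus, vocab)
  ids <- ids[!is.na(ids)]
  counts <- as.integer(keep[vocab])
  vec <- .sgns_train(as.integer(ids) - 1L, counts, as.integer(dim),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), alpha, min_alpha, as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vocab = vocab, vectors = vec,
                 meta = list(dim = dim, window = window, negative = negative,
                             epochs = epochs, min_count = min_count,
                             seed = seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", length(x$vocab), " terms x ", x$meta$dim,
      " dims (window ", x$meta$window, ", k ", x$meta$negative, ", epochs ",
      x$meta$epochs, ", seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' Construct an embedding model from a plain matrix (mainly for tests)
#' @param vectors Numeric matrix with term rownames.
#' @return `embedding_model`.
#' @export
embedding_model <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) stop("duplicate vocabulary terms")
  structure(list(vocab = rownames(vectors), vectors = vectors,
                 meta = list(dim = ncol(vectors))),
            class = "embedding_model")
}

#' Write / read embeddings in word2vec text format
#'
#' First line `vocab_size dim`, then one `term v1 ... vd` line per term, so
#' vectors can be exchanged with any word2vec-compatible tooling.
#'
#' @param model `embedding_model`.
#' @param path File path.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(model$vocab), ncol(model$vectors)), con)
  for (i in seq_along(model$vocab)) {
    writeLines(paste(model$vocab[i],
                     paste(sprintf("%.8g", model$vectors[i, ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  parts <- strsplit(trimws(lines[-1L]), "\\s+")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(vec) <- vocab
  embedding_model(vec)
}

#' Nearest terms by cosine similarity
#'
#' The query term itself is always excluded; ties are broken by lexicographic
#' term order. An out-of-vocabulary term yields an empty result with a
#' warning (expansion is skipped for that term).
#'
#' @param model `embedding_model`.
#' @param term Query term.
#' @param n Number of neighbours (default 5).
#' @return data.frame `term`, `cosine`, at most `n` rows.
#' @export
nearest_terms <- function(model, term, n = 5L) {
  if (n < 1) stop("n must be >= 1")
  i <- match(term, model$vocab)
  if (is.na(i)) {
    warning("term not in embedding vocabulary: ", term)
    return(data.frame(term = character(), cosine = numeric(),
                      stringsAsFactors = FALSE))
  }
  v <- model$vectors[i, ]
  norms <- sqrt(rowSums(model$vectors^2))
  sims <- as.numeric(model$vectors %*% v) / (norms * sqrt(sum(v^2)))
  sims[norms == 0] <- -Inf
  sims[i] <- -Inf
  o <- order(-sims, model$vocab, method = "radix")
  o <- o[seq_len(min(n, length(o)))]
  o <- o[is.finite(sims[o])]
  data.frame(term = model$vocab[o], cosine = sims[o], stringsAsFactors = FALSE)
}

#' Expand a query with embedding neighbours of its medical entities
#'
#' Each extracted entity term contributes its individual word tokens as
#' expansion seeds; every in-vocabulary seed is expanded with its `n` nearest
#' embedding neighbours. The union of neighbours, deduplicated and with
#' original query tokens removed, enters the query at weight `w_exp` while
#' original tokens are reweighted to `w_orig`. Expansion terms participate
#' only in unigram (F) cliques downstream.
#'
#' @param query `weighted_query` from [tagged_query()].
#' @param entity_terms Character vector of extracted entity surfaces (may be
#'   multi-word).
#' @param model `embedding_model`.
#' @param w_orig,w_exp Weights for original / expansion tokens (0.9 / 0.1).
#' @param n Neighbours per seed.
#' @return `weighted_query` with expansion rows appended; attribute
#'   `provenance` maps each expansion term to the seed that produced it.
#' @export
expand_query <- function(query, entity_terms, model, w_orig = 0.9,
                         w_exp = 0.1, n = 5L) {
  stopifnot(inherits(query, "weighted_query"))
  if (w_orig <= 0 || w_orig > 1 || w_exp <= 0 || w_exp > 1)
    stop("weights must lie in (0, 1]")
  query$weight[query$origin == "original"] <- w_orig
  seeds <- unique(unlist(lapply(entity_terms, function(e)
    preprocess(e, stoplist = NULL, split_hyphens = TRUE))))
  exp_terms <- character(0)
  provenance <- character(0)
  for (seed in seeds) {
    if (!seed %in% model$vocab) next
    nn <- nearest_terms(model, seed, n)
    new <- setdiff(nn$term, c(query$term, exp_terms))
    exp_terms <- c(exp_terms, new)
    provenance <- c(provenance, stats::setNames(rep(seed, length(new)), new))
  }
  if (length(exp_terms)) {
    add <- data.frame(term = exp_terms, tag = pos_tag(exp_terms),
                      weight = rep(w_exp, length(exp_terms)),
                      origin = rep("expansion", length(exp_terms)),
                      stringsAsFactors = FALSE)
    out <- rbind(as.data.frame(query), add)
  } else {
    out <- as.data.frame(query)
  }
  structure(out, class = c("weighted_query", "data.frame"),
            query_id = attr(query, "query_id"), provenance = provenance)
}
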