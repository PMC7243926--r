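#' Configuration of one end-to-end system
#'
#' One row of the evaluated 3 x 2 x 2 grid: retrieval model (tfidf / mrf /
#' posmrf) with or without word-embedding query expansion (WE) and with or
#' without entity-overlap re-ranking (RR).
#'
#' @param model "tfidf", "mrf" or "posmrf".
#' @param use_expansion,use_rerank Logical switches.
#' @param tag Run tag; default derived from the setting.
#' @param config [clique_config()].
#' @param weights [pos_weights()] (POS-MRF only).
#' @param retrieval_k Depth of the first-pass retrieval (default 10000).
#' @param final_k Documents kept in the emitted run (default 1000).
#' @param w_orig,w_exp,n_neighbours Expansion parameters.
#' @return `system_config` list.
#' @export
system_config <- function(model = c("posmrf", "mrf", "tfidf"),
                          use_expansion = FALSE, use_rerank = FALSE,
                          tag = NULL, config = clique_config(),
                          weights = pos_weights(), retrieval_k = 10000L,
                          final_k = 1000L, w_orig = 0.9, w_exp = 0.1,
                          n_neighbours = 5L) {
  model <- match.arg(model)
  if (is.null(tag))
    tag <- paste0(model, if (use_expansion) "+WE", if (use_rerank) "+RR")
  structure(list(model = model, use_expansion = use_expansion,
                 use_rerank = use_rerank, tag = tag, config = config,
                 weights = weights, retrieval_k = as.integer(retrieval_k),
                 final_k = as.integer(final_k), w_orig = w_orig,
                 w_exp = w_exp, n_neighbours = as.integer(n_neighbours)),
            class = "system_config")
}

#' The full 12-system grid
#' @inheritParams system_config
#' @return List of 12 [system_config()]s (3 models x +/-WE x +/-RR).
#' @export
all_system_configs <- function(config = clique_config(),
                               weights = pos_weights(),
                               retrieval_k = 10000L, final_k = 1000L) {
  grid <- expand.grid(model = c("tfidf", "mrf", "posmrf"),
                      use_expansion = c(FALSE, TRUE),
                      use_rerank = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    system_config(grid$model[i], grid$use_expansion[i], grid$use_rerank[i],
                  config = config, weights = weights,
                  retrieval_k = retrieval_k, final_k = final_k))
}

# entity mentions for every document, keyed by doc_id (title + description
# concatenated; the join offset is irrelevant because only entity ids are
# compared downstream)
doc_mention_store <- function(docs, dictionary, max_n = 8L) {
  out <- vector("list", length(docs))
  names(out) <- vapply(docs, function(d) d$doc_id, character(1))
  for (i in seq_along(docs)) {
    d <- docs[[i]]
    out[[i]] <- extract_entities(paste(d$title, d$description), dictionary,
                                 max_n = max_n)
  }
  out
}

#' Run one system configuration end to end
#'
#' Expansion (when enabled) precedes retrieval: entity terms extracted from
#' the query seed the embedding neighbours, the weighted query retrieves the
#' top `retrieval_k` documents, optional entity-overlap re-ranking re-scores
#' them, and the top `final_k` are returned (and written as a TREC run when
#' `out` is given).
#'
#' @param sys [system_config()].
#' @param index `two_field_index` of the collection.
#' @param queries data.frame `query_id`, `text`.
#' @param dictionary [entity_dictionary()] for entity extraction.
#' @param embeddings `embedding_model`; required when `sys$use_expansion`.
#' @param doc_mentions Named list doc_id -> mentions (required for
#'   re-ranking; build once with the internal store used by
#'   [run_benchmark()], or via [extract_entities()]).
#' @param out Optional run-file path.
#' @param stoplist Query stoplist.
#' @return List of [ranked_list()]s, one per query.
#' @export
run_system <- function(sys, index, queries, dictionary = NULL,
                       embeddings = NULL, doc_mentions = NULL, out = NULL,
                       stoplist = make_stoplist(query_mode = TRUE)) {
  if (sys$use_expansion && is.null(embeddings))
    stop("configuration ", sys$tag, " needs a trained embedding model; ",
         "train one with train_embeddings(build_training_corpus(docs))")
  if ((sys$use_expansion || sys$use_rerank) && is.null(dictionary))
    stop("configuration ", sys$tag, " needs an entity dictionary")
  if (sys$use_rerank && is.null(doc_mentions))
    stop("configuration ", sys$tag, " needs per-document entity mentions")
  runs <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    qid <- queries$query_id[i]
    tq <- tagged_query(queries$text[i], query_id = qid, stoplist = stoplist)
    q_mentions <- NULL
    if (!is.null(dictionary))
      q_mentions <- extract_entities(queries$text[i], dictionary)
    if (sys$use_expansion) {
      seeds <- if (nrow(q_mentions)) q_mentions$surface else character(0)
      tq <- expand_query(tq, seeds, embeddings, sys$w_orig, sys$w_exp,
                         sys$n_neighbours)
    }
    rl <- retrieve(index, tq, model = sys$model, k = sys$retrieval_k,
                   config = sys$config, weights = sys$weights)
    if (sys$use_rerank) {
      q_ids <- unique(q_mentions$entity_id)
      nd <- vapply(rl$doc_id, function(d) {
        m <- doc_mentions[[d]]
        if (is.null(m)) 0L else length(intersect(q_ids, unique(m$entity_id)))
      }, integer(1))
      rl <- rerank(rl, nd, final_k = sys$final_k)
    } else if (nrow(rl) > sys$final_k) {
      rl <- structure(rl[seq_len(sys$final_k), ],
                      class = c("ranked_list", "data.frame"))
      rl$rank <- seq_len(sys$final_k)
    }
    runs[[i]] <- rl
  }
  names(runs) <- queries$query_id
  if (!is.null(out)) write_run(runs, sys$tag, out, max_per_query = sys$final_k)
  runs
}

#' Run the full 12-system benchmark on one collection
#'
#' Builds the index, trains the embedding model (once) and the per-document
#' entity-mention store (once), runs every configuration, and evaluates each
#' run when qrels are present.
#'
#' @param collection From [generate_collection()], or any list with `docs`,
#'   `queries`, `dictionary` and optionally `qrels`.
#' @param out_dir Directory for run files and evaluation TSVs (optional).
#' @param embedding_seed Seed for [train_embeddings()].
#' @param systems List of [system_config()]s; default the full grid.
#' @param verbose Log stage timings to stderr.
#' @return Named list per system: `runs` and (with qrels) `eval`.
#' @export
run_benchmark <- function(collection, out_dir = NULL, embedding_seed = 1L,
                          systems = all_system_configs(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  index <- build_index(collection$docs)
  say("indexing: %.1fs", proc.time()[["elapsed"]] - t0)
  needs_we <- any(vapply(systems, `[[`, logical(1), "use_expansion"))
  needs_rr <- any(vapply(systems, `[[`, logical(1), "use_rerank"))
  embeddings <- NULL
  if (needs_we) {
    t0 <- proc.time()[["elapsed"]]
    embeddings <- train_embeddings(build_training_corpus(collection$docs),
                                   seed = embedding_seed)
    say("embedding training: %.1fs", proc.time()[["elapsed"]] - t0)
  }
  doc_mentions <- NULL
  if (needs_rr) {
    t0 <- proc.time()[["elapsed"]]
    doc_mentions <- doc_mention_store(collection$docs, collection$dictionary)
    say("document entity extraction: %.1fs", proc.time()[["elapsed"]] - t0)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (sys in systems) {
    t0 <- proc.time()[["elapsed"]]
    out <- if (is.null(out_dir)) NULL
           else file.path(out_dir, paste0(gsub("\\+", "_", sys$tag), ".run"))
    runs <- run_system(sys, index, collection$queries, collection$dictionary,
                       embeddings, doc_mentions, out = out)
    ev <- NULL
    if (!is.null(collection$qrels)) {
      ev <- evaluate_run(runs, collection$qrels)
      if (!is.null(out_dir))
        evaluate_run(runs, collection$qrels,
                     out = file.path(out_dir,
                                     paste0(gsub("\\+", "_", sys$tag),
                                            "_eval.tsv")))
    }
    say("%s: %.1fs", sys$tag, proc.time()[["elapsed"]] - t0)
    results[[sys$tag]] <- list(runs = runs, eval = ev)
  }
  results
}
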