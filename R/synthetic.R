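#' Configuration of the synthetic test collection
#'
#' The generator plants the statistical structure the retrieval system
#' assumes: topical co-occurrence (per-topic Zipf vocabularies over a shared
#' background), synonym families whose two members are distributionally
#' interchangeable (each occurrence is surrounded by the family's dedicated
#' context words, so skip-gram embeddings can recover the pairing), and
#' graded relevance tied to entity presence — grade-2 documents contain the
#' full required entity combination with the entities co-mentioned
#' adjacently, grade-1 documents contain a strict subset scattered without
#' co-mention.
#'
#' @param n_docs Background documents (default 5000).
#' @param n_topics Topics (default 5).
#' @param n_background,n_topic_words Vocabulary sizes.
#' @param n_families Synonym families (pairs of interchangeable entity
#'   tokens; default 10).
#' @param n_family_context Dedicated context words per family.
#' @param n_queries Queries (default 10).
#' @param mean_len,len_dispersion Negative-binomial description length.
#' @param title_len Title length in tokens.
#' @param p_family_episode Probability a background doc carries a family
#'   episode (entity token wrapped in its context words).
#' @param grade2_per_query,grade1_per_query Planted relevant / partially
#'   relevant docs per query.
#' @param n_nonrel_judged Judged non-relevant docs per query.
#' @param synonym_variant_frac Fraction of grade-2 docs phrased with the
#'   synonym partner instead of the query's own entity token.
#' @param background_mix Probability a body token is a background word
#'   (otherwise a topic word).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return `synth_config` list.
#' @export
synth_config <- function(n_docs = 5000L, n_topics = 5L, n_background = 300L,
                         n_topic_words = 120L, n_families = 10L,
                         n_family_context = 8L, n_queries = 10L,
                         mean_len = 80, len_dispersion = 20,
                         title_len = 8L, p_family_episode = 0.5,
                         grade2_per_query = 15L, grade1_per_query = 20L,
                         n_nonrel_judged = 100L,
                         synonym_variant_frac = 0.5,
                         background_mix = 0.45, seed = 7L) {
  cfg <- as.list(environment())
  stopifnot(n_docs > 0, n_topics > 0, n_families > 0, n_queries > 0,
            mean_len > 0, synonym_variant_frac >= 0, synonym_variant_frac <= 1)
  structure(cfg, class = "synth_config")
}

zipf_probs <- function(n) {
  p <- 1 / seq_len(n)
  p / sum(p)
}

#' Generate a synthetic collection with planted relevance
#'
#' @param config [synth_config()].
#' @return List with `docs` (list of [dataset_doc()]), `dictionary`
#'   ([entity_dictionary()]), `queries` (data.frame `query_id`, `text`),
#'   `qrels` (`sampled_qrels`, complete judgments) and `truth` (planted
#'   synonym table and per-query relevance plan).
#' @export
generate_collection <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  bg <- sprintf("bkg%03d", seq_len(cfg$n_background))
  topics <- lapply(seq_len(cfg$n_topics), function(t)
    sprintf("top%d%03d", t, seq_len(cfg$n_topic_words)))
  fam_a <- sprintf("genalpha%02d", seq_len(cfg$n_families))
  fam_b <- sprintf("genbeta%02d", seq_len(cfg$n_families))
  # family context words are ordinary mid-frequency background words
  # (disjoint across families): the two members then share a near-identical
  # episode-context distribution while the context words themselves keep
  # mostly generic contexts, so embeddings pull the members together rather
  # than member towards context
  ctx_offset <- 50L
  if (cfg$n_background < ctx_offset + cfg$n_families * cfg$n_family_context)
    stop("background vocabulary too small for the family context blocks")
  fam_ctx <- lapply(seq_len(cfg$n_families), function(f)
    bg[ctx_offset + (f - 1L) * cfg$n_family_context +
         seq_len(cfg$n_family_context)])
  p_bg <- zipf_probs(cfg$n_background)
  p_top <- zipf_probs(cfg$n_topic_words)

  body_tokens <- function(topic, L) {
    from_bg <- stats::runif(L) < cfg$background_mix
    out <- character(L)
    out[from_bg] <- sample(bg, sum(from_bg), replace = TRUE, prob = p_bg)
    out[!from_bg] <- sample(topics[[topic]], sum(!from_bg), replace = TRUE,
                            prob = p_top)
    out
  }
  episode <- function(f, member) {
    ctx <- sample(fam_ctx[[f]], 3L, replace = FALSE)
    c(ctx[1L], ctx[2L], member, ctx[3L])
  }
  insert_at <- function(body, chunk) {
    pos <- sample.int(length(body) + 1L, 1L)
    append(body, chunk, after = pos - 1L)
  }
  doc_len <- function() {
    max(20L, stats::rnbinom(1L, mu = cfg$mean_len, size = cfg$len_dispersion))
  }

  docs <- vector("list", cfg$n_docs)
  for (i in seq_len(cfg$n_docs)) {
    topic <- sample.int(cfg$n_topics, 1L)
    body <- body_tokens(topic, doc_len())
    if (stats::runif(1) < cfg$p_family_episode) {
      for (rep in seq_len(sample(1:2, 1L))) {
        f <- sample.int(cfg$n_families, 1L)
        member <- if (stats::runif(1) < 0.5) fam_a[f] else fam_b[f]
        body <- insert_at(body, episode(f, member))
      }
    }
    title <- body_tokens(topic, cfg$title_len)
    docs[[i]] <- dataset_doc(sprintf("doc%05d", i),
                             paste(title, collapse = " "),
                             paste(body, collapse = " "))
  }

  # per-query relevance plan: two required entity tokens from two families
  plan <- data.frame(
    query_id = sprintf("q%02d", seq_len(cfg$n_queries)),
    topic = ((seq_len(cfg$n_queries) - 1L) %% cfg$n_topics) + 1L,
    fam1 = ((seq_len(cfg$n_queries) - 1L) %% cfg$n_families) + 1L,
    fam2 = (seq_len(cfg$n_queries) %% cfg$n_families) + 1L,
    stringsAsFactors = FALSE)
  plan$entity1 <- fam_a[plan$fam1]
  plan$entity2 <- fam_a[plan$fam2]
  plan$n_grade2 <- cfg$grade2_per_query
  plan$n_grade1 <- cfg$grade1_per_query

  queries <- data.frame(query_id = plan$query_id, text = NA_character_,
                        stringsAsFactors = FALSE)
  jq <- list()
  for (q in seq_len(cfg$n_queries)) {
    t_q <- plan$topic[q]
    tw <- topics[[t_q]][1:2]
    queries$text[q] <- paste("Find data on", plan$entity1[q], "and",
                             plan$entity2[q], "related to", tw[1L], tw[2L],
                             "in all databases")
    n_var <- floor(cfg$synonym_variant_frac * plan$n_grade2[q])
    for (i in seq_len(plan$n_grade2[q])) {
      e1 <- if (i <= n_var) fam_b[plan$fam1[q]] else plan$entity1[q]
      e2 <- plan$entity2[q]
      body <- body_tokens(t_q, doc_len())
      body <- insert_at(body, c(e1, e2))            # adjacent co-mention
      body <- insert_at(body, episode(plan$fam1[q], e1))
      title <- c(body_tokens(t_q, cfg$title_len - 2L), e1, e2)
      did <- sprintf("rel%02dd%03d", q, i)
      docs[[length(docs) + 1L]] <- dataset_doc(did,
                                               paste(title, collapse = " "),
                                               paste(body, collapse = " "))
      jq[[length(jq) + 1L]] <- data.frame(query_id = plan$query_id[q],
                                          doc_id = did, grade = 2L)
    }
    for (i in seq_len(plan$n_grade1[q])) {
      # strict subset of the combo, scattered without co-mention
      ent <- if (i %% 2L == 0L) plan$entity1[q] else plan$entity2[q]
      body <- insert_at(body_tokens(t_q, doc_len()), ent)
      title <- body_tokens(t_q, cfg$title_len)
      did <- sprintf("par%02dd%03d", q, i)
      docs[[length(docs) + 1L]] <- dataset_doc(did,
                                               paste(title, collapse = " "),
                                               paste(body, collapse = " "))
      jq[[length(jq) + 1L]] <- data.frame(query_id = plan$query_id[q],
                                          doc_id = did, grade = 1L)
    }
    nonrel <- sample(sprintf("doc%05d", seq_len(cfg$n_docs)),
                     min(cfg$n_nonrel_judged, cfg$n_docs))
    jq[[length(jq) + 1L]] <- data.frame(query_id = plan$query_id[q],
                                        doc_id = nonrel, grade = 0L)
  }
  judgments <- data.table::rbindlist(jq)
  dict <- entity_dictionary(
    surface = c(fam_a, fam_b),
    entity_id = paste0("syn:", c(fam_a, fam_b)),
    semantic_type = rep(c("GENE", "DISO", "CHEM", "PROC"),
                        length.out = 2L * cfg$n_families),
    source = "synthetic")
  truth <- list(
    synonyms = data.frame(family = seq_len(cfg$n_families), a = fam_a,
                          b = fam_b, stringsAsFactors = FALSE),
    plan = plan)
  list(docs = docs, dictionary = dict, queries = queries,
       qrels = sampled_qrels(judgments), truth = truth, config = cfg)
}

#' Write a generated collection to disk in the package's exchange formats
#'
#' Produces `datasets.jsonl`, `queries.txt`, `qrels.txt` and
#' `dictionary.tsv` under `dir`, exactly the formats the readers in this
#' package consume.
#'
#' @param collection From [generate_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "datasets.jsonl"), "w")
  for (d in collection$docs) {
    writeLines(jsonlite::toJSON(list(`_id` = d$doc_id,
                                     metadata = list(title = d$title,
                                                     description = d$description)),
                                auto_unbox = TRUE), con)
  }
  close(con)
  writeLines(sprintf("%s\t%s", collection$queries$query_id,
                     collection$queries$text),
             file.path(dir, "queries.txt"))
  j <- collection$qrels$judgments
  writeLines(sprintf("%s 0 %s %d", j$query_id, j$doc_id, j$grade),
             file.path(dir, "qrels.txt"))
  dict <- collection$dictionary
  writeLines(sprintf("%s\t%s\t%s\t%s", dict$key, dict$entity_id,
                     dict$semantic_type, dict$source),
             file.path(dir, "dictionary.tsv"))
  invisible(dir)
}

#' Sample judgments per stratum to drive the inferred measures
#'
#' Draws a uniform without-replacement sample of size `round(rate * pool)`
#' from every (query, stratum) cell and records pool and sample sizes, the
#' metadata [inf_ap()] and [inf_ndcg()] need. Judgments without a stratum
#' column form a single stratum "ALL".
#'
#' @param qrels `sampled_qrels` with complete judgments.
#' @param rate Sampling rate in (0, 1].
#' @param seed Integer seed.
#' @return `sampled_qrels` with sampled judgments, stratum labels and
#'   stratum metadata.
#' @export
sample_qrels <- function(qrels, rate, seed = 1L) {
  if (rate <= 0 || rate > 1) stop("rate must lie in (0, 1]")
  set.seed(seed)
  j <- data.table::copy(qrels$judgments)
  if (!"stratum" %in% names(j)) j[, "stratum" := "ALL"]
  keep <- logical(nrow(j))
  meta <- list()
  cells <- unique(j[, c("query_id", "stratum"), with = FALSE])
  for (r in seq_len(nrow(cells))) {
    idx <- which(j$query_id == cells$query_id[r] &
                   j$stratum == cells$stratum[r])
    n_pool <- length(idx)
    n_samp <- as.integer(round(rate * n_pool))
    if (n_samp == 0L && n_pool > 0L)
      warning("stratum ", cells$stratum[r], " of query ", cells$query_id[r],
              " sampled to emptiness at rate ", rate)
    keep[idx[sample.int(length(idx), n_samp)]] <- TRUE
    meta[[r]] <- data.frame(query_id = cells$query_id[r],
                            stratum = cells$stratum[r],
                            pool_size = n_pool, sample_size = n_samp,
                            stringsAsFactors = FALSE)
  }
  sampled_qrels(j[keep], data.table::rbindlist(meta))
}
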