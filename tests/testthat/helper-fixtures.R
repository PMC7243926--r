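# Fixtures and independent oracles used across the suite.

tiny_docs <- function() {
  list(dataset_doc("d1", "gene gene disease", "protein study"),
       dataset_doc("d2", "disease", ""),
       dataset_doc("d3", "unrelated title", "something else entirely"))
}

# random synthetic documents over a small vocabulary (no stopwords in vocab)
random_docs <- function(n, vocab = sprintf("w%02d", 1:30), min_len = 3,
                        max_len = 25) {
  lapply(seq_len(n), function(i) {
    lt <- sample(min_len:max_len, 1)
    ld <- sample(0:max_len, 1)
    dataset_doc(sprintf("rd%03d", i),
                paste(sample(vocab, lt, replace = TRUE), collapse = " "),
                if (ld == 0) "" else
                  paste(sample(vocab, ld, replace = TRUE), collapse = " "))
  })
}

qrels_from_df <- function(df, stratum_meta = NULL) {
  sampled_qrels(df, stratum_meta)
}

# one random (ranking, qrels) evaluation instance
random_eval_case <- function(n_docs = 30, n_rel = NULL) {
  docs <- sprintf("e%03d", seq_len(n_docs))
  grades <- sample(0:2, n_docs, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  judged <- sort(sample(n_docs, max(2, rbinom(1, n_docs, 0.8))))
  qr <- qrels_from_df(data.frame(query_id = "q1", doc_id = docs[judged],
                                 grade = grades[judged]))
  ranking <- sample(docs, sample(5:n_docs, 1))
  list(ranking = ranking, qrels = qr)
}

# --- definitional metric oracles (independent of the package's code paths) ---

oracle_ap <- function(ranking, grades, thr = 1) {
  rel <- names(grades)[grades >= thr]
  if (length(rel) == 0) return(NA_real_)
  hits <- 0
  s <- 0
  for (k in seq_along(ranking)) {
    if (ranking[k] %in% rel) {
      hits <- hits + 1
      s <- s + hits / k
    }
  }
  s / length(rel)
}

oracle_p_at_k <- function(ranking, grades, k, thr) {
  cnt <- 0
  for (i in seq_len(k)) {
    if (i <= length(ranking)) {
      g <- grades[ranking[i]]
      if (!is.na(g) && g >= thr) cnt <- cnt + 1
    }
  }
  cnt / k
}

oracle_ndcg <- function(ranking, grades, k) {
  gain <- function(v) {
    s <- 0
    for (i in seq_along(v)) s <- s + unname(v[i]) / log2(i + 1)
    s
  }
  g <- numeric(min(k, length(ranking)))
  for (i in seq_along(g)) {
    gr <- grades[ranking[i]]
    g[i] <- if (is.na(gr)) 0 else gr
  }
  ideal <- sort(grades, decreasing = TRUE)
  ideal <- ideal[seq_len(min(k, length(ideal)))]
  if (gain(ideal) == 0) return(NA_real_)
  gain(g) / gain(ideal)
}

# brute-force dense-vector cosine for tf-idf over a single field
oracle_tfidf_cosine <- function(query_tokens, doc_tokens_list, target_doc) {
  vocab <- unique(c(query_tokens, unlist(doc_tokens_list)))
  N <- length(doc_tokens_list)
  df <- sapply(vocab, function(t)
    sum(sapply(doc_tokens_list, function(d) t %in% d)))
  idf <- ifelse(df > 0, log(N / df), 0)
  vec <- function(tokens) {
    tf <- sapply(vocab, function(t) sum(tokens == t))
    ifelse(tf > 0, (1 + log(tf)) * idf, 0)
  }
  qv <- vec(query_tokens)
  dv <- vec(doc_tokens_list[[target_doc]])
  if (sqrt(sum(dv^2)) == 0 || sqrt(sum(qv^2)) == 0) return(0)
  sum(qv * dv) / (sqrt(sum(qv^2)) * sqrt(sum(dv^2)))
}

# brute-force ordered/unordered pair counting by full O(n^2) scan
oracle_count_ordered <- function(p1, p2, w) {
  n <- 0
  for (a in p1) for (b in p2) if (b - a > 0 && b - a <= w) n <- n + 1
  n
}
oracle_count_unordered <- function(p1, p2, w) {
  n <- 0
  for (a in p1) for (b in p2) if (abs(b - a) < w) n <- n + 1
  n
}

# brute-force MRF scorer computed directly from raw token lists, never
# touching the package's index or potential functions
oracle_mrf_score <- function(query_terms, doc_tokens_list, target_doc,
                             theta = c(0.8, 0.1, 0.1), mu = 2500,
                             win_o = 1, win_u = 8, lambda = NULL,
                             qweights = NULL) {
  if (is.null(lambda)) lambda <- rep(1, length(query_terms))
  if (is.null(qweights)) qweights <- rep(1, length(query_terms))
  clen <- sum(lengths(doc_tokens_list))
  dtoks <- doc_tokens_list[[target_doc]]
  dlen <- length(dtoks)
  pot <- function(tf, ctf) {
    pc <- if (ctf == 0) 1 / (clen + 1) else ctf / clen
    log((tf + mu * pc) / (dlen + mu))
  }
  pos_of <- function(tokens, t) which(tokens == t) - 1L
  s <- 0
  for (i in seq_along(query_terms)) {
    t <- query_terms[i]
    tf <- sum(dtoks == t)
    ctf <- sum(sapply(doc_tokens_list, function(d) sum(d == t)))
    s <- s + theta[1] * lambda[i] * qweights[i] * pot(tf, ctf)
  }
  pair_ct <- function(tokens, t1, t2, w, ordered) {
    p1 <- pos_of(tokens, t1); p2 <- pos_of(tokens, t2)
    if (ordered) oracle_count_ordered(p1, p2, w)
    else oracle_count_unordered(p1, p2, w)
  }
  if (length(query_terms) >= 2) {
    for (i in seq_len(length(query_terms) - 1)) {
      lam <- mean(lambda[c(i, i + 1)]); qw <- mean(qweights[c(i, i + 1)])
      tf <- pair_ct(dtoks, query_terms[i], query_terms[i + 1], win_o, TRUE)
      ctf <- sum(sapply(doc_tokens_list, pair_ct, query_terms[i],
                        query_terms[i + 1], win_o, TRUE))
      s <- s + theta[2] * lam * qw * pot(tf, ctf)
    }
    cmb <- combn(length(query_terms), 2)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      lam <- mean(lambda[c(i1, i2)]); qw <- mean(qweights[c(i1, i2)])
      tf <- pair_ct(dtoks, query_terms[i1], query_terms[i2], win_u, FALSE)
      ctf <- sum(sapply(doc_tokens_list, pair_ct, query_terms[i1],
                        query_terms[i2], win_u, FALSE))
      s <- s + theta[3] * lam * qw * pot(tf, ctf)
    }
  }
  s
}

# small synthetic collection for pipeline tests (fast)
small_collection <- function(seed = 11) {
  generate_collection(synth_config(
    n_docs = 250, n_queries = 3, grade2_per_query = 5, grade1_per_query = 5,
    n_nonrel_judged = 30, mean_len = 40, seed = seed))
}

expect_valid_run <- function(runs, final_k) {
  for (rl in runs) {
    expect_lte(nrow(rl), final_k)
    if (nrow(rl) > 0) {
      expect_identical(rl$rank, seq_len(nrow(rl)))
      expect_true(all(diff(rl$score) <= 1e-12))
      expect_false(anyDuplicated(rl$doc_id) > 0)
    }
  }
}
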