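#' Clique configuration for the MRF ranking family
#'
#' Holds the dependence-type weights and smoothing constants of the ranking
#' function r(Q,D) = sum_c theta_c * sum_cliques lambda * w * log f(c, q, D)
#' over the three clique sets: full independence (F, unigrams), sequential
#' dependence (O, adjacent ordered pairs) and full dependence (U, unordered
#' pairs).
#'
#' @param theta_F,theta_O,theta_U Non-negative clique-set weights
#'   (defaults 0.8 / 0.1 / 0.1).
#' @param dirichlet_mu Dirichlet smoothing mass (> 0), default 2500.
#' @param ordered_window Window for ordered pair counts (adjacent bigrams: 1).
#' @param unordered_window Window for unordered pair counts (default 8).
#' @param field_weights Length-2 weights for combining per-field scores
#'   (title, description); default equal.
#' @return `clique_config` list.
#' @export
clique_config <- function(theta_F = 0.8, theta_O = 0.1, theta_U = 0.1,
                          dirichlet_mu = 2500, ordered_window = 1L,
                          unordered_window = 8L,
                          field_weights = c(title = 0.5, description = 0.5)) {
  stopifnot(theta_F >= 0, theta_O >= 0, theta_U >= 0, dirichlet_mu > 0,
            length(field_weights) == 2L)
  structure(list(theta = c(F = theta_F, O = theta_O, U = theta_U),
                 dirichlet_mu = dirichlet_mu,
                 ordered_window = as.integer(ordered_window),
                 unordered_window = as.integer(unordered_window),
                 field_weights = field_weights),
            class = "clique_config")
}

#' Part-of-speech term weights
#'
#' One lambda per Penn tag class; the defaults are the constants optimized on
#' the TREC 2011/2012 Medical Records collections: nouns 0.5970, plural nouns
#' 0.2265, past-participle verbs 0.3065, past-tense verbs 0.2260, adjectives
#' 0.3730, adverbs 0.1040, singular proper nouns 0.8930 and 0.0 for every
#' other category (including base/gerund verb forms, which the weight table
#' does not cover).
#'
#' @param ... Named overrides, e.g. `NN = 1`.
#' @return Named numeric vector with classes NN, NNS, VBN, VBD, JJ, RB, NNP,
#'   OTHER.
#' @export
pos_weights <- function(...) {
  w <- c(NN = 0.5970, NNS = 0.2265, VBN = 0.3065, VBD = 0.2260,
         JJ = 0.3730, RB = 0.1040, NNP = 0.8930, OTHER = 0.0)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(w))
    if (length(bad)) stop("unknown POS class: ", paste(bad, collapse = ", "))
    w[names(ov)] <- unlist(ov)
  }
  if (any(w < 0 | w > 1)) stop("lambda values must lie in [0,1]")
  w
}

#' Uniform lambda weights (reduces POS-MRF to plain MRF)
#' @return `pos_weights()` with every class set to 1.
#' @export
uniform_pos_weights <- function() {
  w <- pos_weights(); w[] <- 1; w
}

#' Look up the lambda weight for a tag
#'
#' Exact class match (NN, NNS, VBN, VBD, JJ, RB, NNP); anything else maps to
#' OTHER.
#'
#' @param tag Penn tag string (vectorized).
#' @param weights From [pos_weights()].
#' @return Numeric lambda(s).
#' @export
lambda_for <- function(tag, weights = pos_weights()) {
  cls <- ifelse(tag %in% setdiff(names(weights), "OTHER"), tag, "OTHER")
  unname(weights[cls])
}

#' Build a tagged, weighted query
#'
#' Preprocesses the raw query text with the query-mode stoplist (which adds
#' "find" and "search"), tags the surviving tokens, and assigns each the given
#' weight. Expansion terms are added later by [expand_query()].
#'
#' @param text Raw query string, or an already-tokenized character vector.
#' @param query_id Identifier carried through to ranked lists.
#' @param stoplist Stoplist (default query mode).
#' @param tagger Optional tagger override for [pos_tag()].
#' @param weight Per-token weight for original terms.
#' @param tokenized Treat `text` as ready-made tokens, skipping
#'   preprocessing; default when more than one element is supplied.
#' @return `weighted_query`: data.frame with columns `term`, `tag`, `weight`,
#'   `origin`; attribute `query_id`.
#' @export
tagged_query <- function(text, query_id = "q",
                         stoplist = make_stoplist(query_mode = TRUE),
                         tagger = NULL, weight = 1.0,
                         tokenized = length(text) > 1L) {
  toks <- if (tokenized) text else preprocess(text, stoplist)
  if (length(toks) == 0L) {
    q <- data.frame(term = character(), tag = character(), weight = numeric(),
                    origin = character(), stringsAsFactors = FALSE)
  } else {
    q <- data.frame(term = toks, tag = pos_tag(toks, tagger),
                    weight = rep(weight, length(toks)),
                    origin = rep("original", length(toks)),
                    stringsAsFactors = FALSE)
  }
  structure(q, class = c("weighted_query", "data.frame"), query_id = query_id)
}

floor_prob <- function(fi) 1 / (fi$collection_length + 1)

#' Dirichlet-smoothed unigram log potential
#'
#' log((tf + mu * P(term|C)) / (|D| + mu)), with the collection probability
#' floored at 1/(collection_length + 1) for terms absent from the whole
#' collection, so every potential stays finite.
#'
#' @param term Query term.
#' @param doc_id Document identifier.
#' @param field_index One `field_index` from [build_index()].
#' @param mu Dirichlet smoothing mass.
#' @return Log potential (finite).
#' @export
potential_F <- function(term, doc_id, field_index, mu = 2500) {
  if (field_index$collection_length == 0)
    stop("potential_F on an empty collection")
  p <- field_index$postings[[term]]
  tf <- if (is.null(p) || is.null(p[[doc_id]])) 0 else length(p[[doc_id]])
  ctf <- field_index$collection_tf[term]
  pc <- if (is.na(ctf) || ctf == 0) floor_prob(field_index)
        else ctf / field_index$collection_length
  len <- field_index$doc_length[[doc_id]]
  unname(log((tf + mu * pc) / (len + mu)))
}

# per-field co-occurrence statistics for one term pair
pair_counts <- function(fi, t1, t2, type = c("O", "U"), window) {
  type <- match.arg(type)
  p1 <- fi$postings[[t1]]; p2 <- fi$postings[[t2]]
  if (is.null(p1) || is.null(p2))
    return(list(counts = numeric(0), ctf = 0))
  docs <- intersect(names(p1), names(p2))
  if (length(docs) == 0L) return(list(counts = numeric(0), ctf = 0))
  cf <- if (type == "O") count_ordered else count_unordered
  counts <- vapply(docs, function(d) as.numeric(cf(p1[[d]], p2[[d]], window)),
                   numeric(1))
  counts <- counts[counts > 0]
  list(counts = counts, ctf = sum(counts))
}

#' Dirichlet-smoothed ordered-pair log potential
#'
#' The pair pseudo-term frequency is [count_ordered()] of the two position
#' lists; collection statistics are the same counts summed over the whole
#' field.
#'
#' @param term1,term2 Adjacent query terms, in order.
#' @inheritParams potential_F
#' @param config [clique_config()] providing mu and the window.
#' @return Log potential.
#' @export
potential_O <- function(term1, term2, doc_id, field_index,
                        config = clique_config()) {
  ps <- pair_counts(field_index, term1, term2, "O", config$ordered_window)
  pair_potential(ps, doc_id, field_index, config$dirichlet_mu)
}

#' Dirichlet-smoothed unordered-pair log potential
#' @inheritParams potential_O
#' @export
potential_U <- function(term1, term2, doc_id, field_index,
                        config = clique_config()) {
  ps <- pair_counts(field_index, term1, term2, "U", config$unordered_window)
  pair_potential(ps, doc_id, field_index, config$dirichlet_mu)
}

pair_potential <- function(ps, doc_id, fi, mu) {
  tf <- if (doc_id %in% names(ps$counts)) ps$counts[[doc_id]] else 0
  pc <- if (ps$ctf == 0) floor_prob(fi) else ps$ctf / fi$collection_length
  len <- fi$doc_length[[doc_id]]
  log((tf + mu * pc) / (len + mu))
}

# ---- vectorized per-field scoring over a candidate set -----------------------

# lambda multipliers per query row: 1 for mrf/ql/tfidf, POS lambda for posmrf
query_lambdas <- function(qdf, model, weights) {
  if (model == "posmrf") lambda_for(qdf$tag, weights) else rep(1, nrow(qdf))
}

score_field_lm <- function(fi, qdf, cand, model, config, weights) {
  mu <- config$dirichlet_mu
  len <- fi$doc_length[cand]
  scores <- numeric(length(cand))
  lam <- query_lambdas(qdf, model, weights)
  theta <- if (model == "ql") c(F = 1, O = 0, U = 0) else config$theta
  # F cliques: every query token (original and expansion)
  for (i in seq_len(nrow(qdf))) {
    term <- qdf$term[i]
    wm <- theta[["F"]] * lam[i] * qdf$weight[i]
    if (wm == 0) next
    p <- fi$postings[[term]]
    tf <- numeric(length(cand))
    if (!is.null(p)) {
      hit <- match(names(p), cand)
      ok <- !is.na(hit)
      tf[hit[ok]] <- lengths(p)[ok]
    }
    ctf <- fi$collection_tf[term]
    pc <- if (is.na(ctf) || ctf == 0) floor_prob(fi)
          else ctf / fi$collection_length
    scores <- scores + wm * log((tf + mu * pc) / (len + mu))
  }
  if (theta[["O"]] == 0 && theta[["U"]] == 0) return(scores)
  orig <- qdf[qdf$origin == "original", , drop = FALSE]
  lam_o <- query_lambdas(orig, model, weights)
  add_pairs <- function(pairs, type, window, th) {
    if (th == 0 || nrow(pairs) == 0L) return()
    for (j in seq_len(nrow(pairs))) {
      i1 <- pairs$i1[j]; i2 <- pairs$i2[j]
      wm <- th * mean(c(lam_o[i1], lam_o[i2])) *
        mean(c(orig$weight[i1], orig$weight[i2]))
      if (wm == 0) next
      ps <- pair_counts(fi, orig$term[i1], orig$term[i2], type, window)
      tf <- numeric(length(cand))
      if (length(ps$counts)) {
        hit <- match(names(ps$counts), cand)
        ok <- !is.na(hit)
        tf[hit[ok]] <- ps$counts[ok]
      }
      pc <- if (ps$ctf == 0) floor_prob(fi) else ps$ctf / fi$collection_length
      scores <<- scores + wm * log((tf + mu * pc) / (len + mu))
    }
  }
  n <- nrow(orig)
  if (n >= 2L) {
    adj <- data.frame(i1 = seq_len(n - 1L), i2 = seq_len(n - 1L) + 1L)
    add_pairs(adj, "O", config$ordered_window, theta[["O"]])
    cmb <- utils::combn(n, 2L)
    unord <- data.frame(i1 = cmb[1L, ], i2 = cmb[2L, ])
    add_pairs(unord, "U", config$unordered_window, theta[["U"]])
  }
  scores
}

score_field_tfidf <- function(fi, qdf, cand) {
  N <- fi$doc_count
  if (N == 0L) return(numeric(length(cand)))
  # query vector: weight-scaled term frequencies
  qtf <- tapply(qdf$weight, qdf$term, sum)
  terms <- names(qtf)
  df <- fi$df[terms]
  keep <- !is.na(df) & df > 0 & df < N | (!is.na(df) & df == N)
  idf <- ifelse(is.na(df) | df == 0, 0, log(N / pmax(df, 1)))
  qw <- (1 + log(pmax(as.numeric(qtf), 1e-12))) * idf
  qnorm <- sqrt(sum(qw^2))
  dots <- numeric(length(cand))
  for (i in seq_along(terms)) {
    if (qw[i] == 0) next
    p <- fi$postings[[terms[i]]]
    if (is.null(p)) next
    tf <- numeric(length(cand))
    hit <- match(names(p), cand)
    ok <- !is.na(hit)
    tf[hit[ok]] <- lengths(p)[ok]
    dw <- ifelse(tf > 0, (1 + log(tf)) * idf[i], 0)
    dots <- dots + qw[i] * dw
  }
  dnorm <- fi$tfidf_norm[cand]
  denom <- qnorm * dnorm
  ifelse(denom > 0, dots / denom, 0)
}

# document-vector norms under (1 + log tf) * log(N/df); computed on demand
tfidf_norms <- function(fi) {
  if (!is.null(fi$tfidf_norm)) return(fi)
  norms <- stats::setNames(numeric(length(fi$doc_ids)), fi$doc_ids)
  N <- fi$doc_count
  for (term in names(fi$postings)) {
    idf <- log(N / fi$df[[term]])
    if (idf == 0) next
    p <- fi$postings[[term]]
    w2 <- ((1 + log(lengths(p))) * idf)^2
    norms[names(p)] <- norms[names(p)] + w2
  }
  fi$tfidf_norm <- sqrt(norms)
  fi
}

#' Score one document under the POS-weighted MRF
#'
#' r(Q,D) = sum over c in {F,O,U} of theta_c * sum over cliques of
#' lambda(clique) * w(clique) * log f(c, clique, D), where lambda of a pair
#' clique is the mean of its members' lambdas, w is the query-term weight
#' (0.9/0.1 under expansion), and the two field scores are combined by
#' `config$field_weights`. Expansion terms participate only in F cliques.
#'
#' @param query `weighted_query`.
#' @param doc_id Document to score.
#' @param index `two_field_index`.
#' @param config [clique_config()].
#' @param weights [pos_weights()].
#' @return Numeric score (0, with a warning, for an empty query).
#' @export
score_posmrf <- function(query, doc_id, index, config = clique_config(),
                         weights = pos_weights()) {
  score_one(query, doc_id, index, "posmrf", config, weights)
}

#' Score one document under the unweighted MRF (lambda = 1)
#' @inheritParams score_posmrf
#' @export
score_mrf <- function(query, doc_id, index, config = clique_config()) {
  score_one(query, doc_id, index, "mrf", config, NULL)
}

#' Score one document under Dirichlet query likelihood
#' @inheritParams score_posmrf
#' @export
score_ql <- function(query, doc_id, index, config = clique_config()) {
  score_one(query, doc_id, index, "ql", config, NULL)
}

#' Score one document under cosine TF-IDF
#'
#' Term weights (1 + log tf) * log(N/df) on both sides; per-field cosines are
#' combined with `config$field_weights`.
#' @inheritParams score_posmrf
#' @export
score_tfidf <- function(query, doc_id, index, config = clique_config()) {
  score_one(query, doc_id, index, "tfidf", config, NULL)
}

score_one <- function(query, doc_id, index, model, config, weights) {
  if (nrow(query) == 0L) {
    warning("empty query: score defined as 0")
    return(0)
  }
  fw <- config$field_weights
  total <- 0
  for (fn in 1:2) {
    fi <- index[[fn]]
    s <- if (model == "tfidf") {
      fi <- tfidf_norms(fi)
      score_field_tfidf(fi, query, doc_id)
    } else {
      score_field_lm(fi, query, doc_id, model, config, weights)
    }
    total <- total + fw[[fn]] * s
  }
  unname(total)
}

#' Retrieve the top-K documents for a query
#'
#' Candidates are all documents containing at least one query term (original
#' or expansion) in either field; floor-only documents (no term match at all)
#' are excluded. Ties are broken by ascending doc_id.
#'
#' @param index `two_field_index`.
#' @param query `weighted_query` (or raw text, which is passed through
#'   [tagged_query()]).
#' @param model One of "tfidf", "ql", "mrf", "posmrf".
#' @param k Number of documents to return (default 10000).
#' @param config [clique_config()].
#' @param weights [pos_weights()] (POS-MRF only).
#' @return [ranked_list()] of at most `k` documents.
#' @export
retrieve <- function(index, query, model = c("posmrf", "mrf", "ql", "tfidf"),
                     k = 10000L, config = clique_config(),
                     weights = pos_weights()) {
  model <- match.arg(model)
  if (is.character(query)) query <- tagged_query(query)
  if (k < 1) stop("k must be >= 1")
  qid <- attr(query, "query_id") %||% "q"
  if (nrow(query) == 0L) {
    warning("empty query ", qid, ": no documents retrieved")
    return(ranked_list(qid, character(0), numeric(0)))
  }
  cand <- character(0)
  for (fn in 1:2) {
    post <- index[[fn]]$postings
    for (term in unique(query$term)) {
      p <- post[[term]]
      if (!is.null(p)) cand <- c(cand, names(p))
    }
  }
  cand <- unique(cand)
  if (length(cand) == 0L) return(ranked_list(qid, character(0), numeric(0)))
  fw <- config$field_weights
  total <- numeric(length(cand))
  for (fn in 1:2) {
    fi <- index[[fn]]
    s <- if (model == "tfidf") {
      fi <- tfidf_norms(fi)
      score_field_tfidf(fi, query, cand)
    } else {
      score_field_lm(fi, query, cand, model, config, weights)
    }
    total <- total + fw[[fn]] * s
  }
  rl <- ranked_list(qid, cand, total)
  if (nrow(rl) > k) rl <- structure(rl[seq_len(k), ],
                                    class = c("ranked_list", "data.frame"))
  rl$rank <- seq_len(nrow(rl))
  rl
}
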