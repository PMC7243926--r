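# plain-data.frame subsetting: inside data.table's `[` the bare qid would be
# resolved against the columns first
query_grades <- function(qrels, qid) {
  j <- as.data.frame(qrels$judgments)
  j <- j[j$query_id == qid, , drop = FALSE]
  stats::setNames(j$grade, j$doc_id)
}

query_strata <- function(qrels, qid) {
  j <- as.data.frame(qrels$judgments)
  j <- j[j$query_id == qid, , drop = FALSE]
  if ("stratum" %in% names(j)) stats::setNames(j$stratum, j$doc_id)
  else stats::setNames(rep("ALL", nrow(j)), j$doc_id)
}

# per-stratum inflation weights pool/sample; 1 everywhere when no sampling
# metadata is recorded (judgments treated as the complete pool)
stratum_weights <- function(qrels, qid) {
  sm <- as.data.frame(qrels$stratum_meta)
  sm <- sm[sm$query_id == qid, , drop = FALSE]
  if (nrow(sm) == 0L) return(NULL)
  w <- sm$pool_size / pmax(sm$sample_size, 1L)
  stats::setNames(w, sm$stratum)
}

#' Average precision of a ranking against graded judgments
#'
#' Mean, over the relevant documents, of precision at their ranks;
#' unretrieved relevant documents contribute 0 and unjudged retrieved
#' documents count as non-relevant.
#'
#' @param ranking Character vector of doc_ids in rank order.
#' @param qrels `sampled_qrels`.
#' @param query_id Query to evaluate.
#' @param rel_threshold Grade counting as relevant (1 counts partial, the
#'   default; 2 restricts to fully relevant).
#' @return AP in `[0,1]`, or `NA` with a warning when the query has no
#'   relevant judged document.
#' @export
average_precision <- function(ranking, qrels, query_id, rel_threshold = 1L) {
  stopifnot(rel_threshold %in% c(1L, 2L))
  grades <- query_grades(qrels, query_id)
  rel <- names(grades)[grades >= rel_threshold]
  if (length(rel) == 0L) {
    warning("query ", query_id, " has no relevant judged docs; AP undefined")
    return(NA_real_)
  }
  hits <- which(ranking %in% rel)
  if (length(hits) == 0L) return(0)
  sum(seq_along(hits) / hits) / length(rel)
}

#' Precision at k, with or without partially relevant documents
#'
#' @inheritParams average_precision
#' @param k Cutoff (default 10); rankings shorter than `k` are padded as
#'   non-relevant.
#' @param include_partial Count grade 1 as relevant (`+partial`); otherwise
#'   only grade 2 counts (`-partial`).
#' @return Precision in `[0,1]`.
#' @export
precision_at_k <- function(ranking, qrels, query_id, k = 10L,
                           include_partial = TRUE) {
  if (k < 1) stop("k must be >= 1")
  grades <- query_grades(qrels, query_id)
  top <- utils::head(ranking, k)
  g <- grades[top]
  g[is.na(g)] <- 0L
  thr <- if (include_partial) 1L else 2L
  sum(g >= thr) / k
}

#' NDCG at k with linear gains
#'
#' DCG with gain = grade and discount 1/log2(rank + 1), normalized by the
#' ideal DCG over all judged documents of the query.
#'
#' @inheritParams precision_at_k
#' @return NDCG in `[0,1]`, or `NA` with a warning when the ideal DCG is 0.
#' @export
ndcg_at_k <- function(ranking, qrels, query_id, k = 10L) {
  if (k < 1) stop("k must be >= 1")
  grades <- query_grades(qrels, query_id)
  ideal <- sort(grades, decreasing = TRUE)
  idcg <- dcg(utils::head(as.numeric(ideal), k))
  if (idcg == 0) {
    warning("query ", query_id, " has ideal DCG 0; NDCG undefined")
    return(NA_real_)
  }
  g <- grades[utils::head(ranking, k)]
  g[is.na(g)] <- 0L
  dcg(as.numeric(g)) / idcg
}

dcg <- function(gains) {
  if (length(gains) == 0L) return(0)
  sum(gains / log2(seq_along(gains) + 1))
}

#' Inferred average precision from sampled judgments
#'
#' Sample-based estimator of expected AP: for each sampled relevant document
#' at rank k, E\[P@k\] = 1/k + ((k-1)/k) * (judged_above/(k-1)) *
#' ((rel_above + eps)/(judged_above + 2*eps)) with eps = 1e-5; with sampling
#' metadata present, judged counts above k and the total-relevant estimate
#' are inflated per stratum by pool_size/sample_size (and each sampled
#' relevant document's contribution is weighted the same way). With complete
#' judgments (sample == pool, or no metadata) it reduces to
#' [average_precision()] at threshold 1 within 1e-6. Relevance is binary at
#' grade >= 1.
#'
#' @inheritParams average_precision
#' @param eps Smoothing constant.
#' @return Estimated AP in `[0,1]`, `NA` with a warning if the sample holds
#'   no relevant document.
#' @export
inf_ap <- function(ranking, qrels, query_id, eps = 1e-5) {
  grades <- query_grades(qrels, query_id)
  if (length(grades) == 0L) {
    warning("query ", query_id, " unjudged; infAP undefined")
    return(NA_real_)
  }
  strata <- query_strata(qrels, query_id)
  w <- stratum_weights(qrels, query_id)
  if (is.null(w)) w <- stats::setNames(rep(1, length(unique(strata))),
                                       unique(strata))
  wdoc <- w[strata]; wdoc[is.na(wdoc)] <- 1
  names(wdoc) <- names(strata)
  rel <- grades >= 1L
  R_hat <- sum(wdoc[rel])
  if (R_hat == 0) {
    warning("query ", query_id, " sample has no relevant docs; infAP 0")
    return(0)
  }
  judged_mask <- ranking %in% names(grades)
  rel_mask <- judged_mask & ranking %in% names(grades)[rel]
  strat_r <- strata[ranking]
  grade_r <- grades[ranking]
  acc <- 0
  for (k in which(rel_mask)) {
    if (k == 1L) {
      epk <- 1
    } else {
      above <- seq_len(k - 1L)
      ja <- above[judged_mask[above]]
      est_rel_above <- 0
      if (length(ja)) {
        for (s in unique(strat_r[ja])) {
          in_s <- ja[strat_r[ja] == s]
          n_s <- length(in_s)
          r_s <- sum(grade_r[in_s] >= 1L)
          ws <- if (s %in% names(w)) w[[s]] else 1
          # the eps smoothing guards sampled strata; a complete stratum
          # (weight 1) needs none, which keeps the complete-judgment
          # reduction to AP exact
          est_rel_above <- est_rel_above + if (ws == 1) r_s
            else ws * n_s * (r_s + eps) / (n_s + 2 * eps)
        }
      }
      est_rel_above <- min(est_rel_above, k - 1)
      epk <- (1 + est_rel_above) / k
    }
    acc <- acc + wdoc[[ranking[k]]] * epk
  }
  min(1, max(0, acc / R_hat))
}

#' Inferred NDCG from sampled judgments
#'
#' DCG is estimated by weighting each judged gain in the ranking by its
#' stratum's inverse sampling rate (pool/sample); the ideal DCG is built from
#' the per-grade counts inflated the same way, filled greedily over ranks
#' with fractional boundary mass. With complete judgments it reduces to
#' [ndcg_at_k()] within 1e-6.
#'
#' @inheritParams precision_at_k
#' @param k_cut DCG cutoff; `Inf` (default) evaluates the whole ranking.
#' @return Estimated NDCG in `[0,1]`; 0 with a warning if the sample holds no
#'   relevant document.
#' @export
inf_ndcg <- function(ranking, qrels, query_id, k_cut = Inf) {
  grades <- query_grades(qrels, query_id)
  if (length(grades) == 0L) {
    warning("query ", query_id, " unjudged; infNDCG undefined")
    return(NA_real_)
  }
  strata <- query_strata(qrels, query_id)
  w <- stratum_weights(qrels, query_id)
  if (is.null(w)) w <- stats::setNames(rep(1, length(unique(strata))),
                                       unique(strata))
  wdoc <- w[strata]; wdoc[is.na(wdoc)] <- 1
  names(wdoc) <- names(strata)
  m2 <- sum(wdoc[grades == 2L]); m1 <- sum(wdoc[grades == 1L])
  if (m2 + m1 == 0) {
    warning("query ", query_id, " sample has no relevant docs; infNDCG 0")
    return(0)
  }
  upto <- min(length(ranking), k_cut)
  g <- grades[ranking[seq_len(upto)]]
  wg <- wdoc[ranking[seq_len(upto)]]
  gains <- ifelse(is.na(g), 0, as.numeric(g) * wg)
  dcg_hat <- sum(gains / log2(seq_len(upto) + 1))
  idcg_hat <- idcg_fractional(m2, m1, k_cut)
  if (idcg_hat == 0) return(0)
  min(1, max(0, dcg_hat / idcg_hat))
}

# ideal DCG from (possibly fractional) estimated grade counts: pour grade-2
# mass, then grade-1 mass, one rank-unit at a time
idcg_fractional <- function(m2, m1, k_cut = Inf) {
  total <- 0
  r <- 1
  rem2 <- m2; rem1 <- m1
  while (r <= k_cut && (rem2 > 1e-12 || rem1 > 1e-12)) {
    a <- min(1, rem2)
    b <- min(1 - a, rem1)
    total <- total + (2 * a + b) / log2(r + 1)
    rem2 <- rem2 - a
    rem1 <- rem1 - b
    r <- r + 1
  }
  total
}

#' Evaluate a run against qrels with all six measures
#'
#' Computes MAP (grade >= 1), P@10 with and without partial relevance,
#' NDCG@10, infAP and infNDCG per query, plus counts of judged and unjudged
#' retrieved documents. Mean rows average over queries with at least one
#' relevant judged document.
#'
#' @param run A run data.frame from [read_run()], a path to a TREC run file,
#'   or a list of [ranked_list()]s.
#' @param qrels `sampled_qrels` or a path to a qrels file.
#' @param k Cutoff for P@k / NDCG@k.
#' @param out Optional path; when given, the table is written as TSV (per
#'   query plus a `mean` row).
#' @return `eval_result`: data.frame with one row per query and attribute
#'   `mean` (named numeric).
#' @export
evaluate_run <- function(run, qrels, k = 10L, out = NULL) {
  if (is.character(run)) run <- read_run(run)
  if (is.character(qrels)) qrels <- read_qrels(qrels)
  if (is.list(run) && !is.data.frame(run)) {
    run <- do.call(rbind, lapply(run, as.data.frame))
  }
  qids_run <- unique(run$query_id)
  qids_q <- unique(qrels$judgments$query_id)
  qids <- intersect(qids_run, qids_q)
  if (length(qids) == 0L) stop("run and qrels share no queries")
  rows <- lapply(sort(qids), function(qid) {
    sub <- run[run$query_id == qid, , drop = FALSE]
    ranking <- sub$doc_id[order(sub$rank)]
    grades <- query_grades(qrels, qid)
    judged <- sum(ranking %in% names(grades))
    data.frame(
      query_id = qid,
      map = suppressWarnings(average_precision(ranking, qrels, qid, 1L)),
      p10_plus = precision_at_k(ranking, qrels, qid, k, TRUE),
      p10_minus = precision_at_k(ranking, qrels, qid, k, FALSE),
      ndcg10 = suppressWarnings(ndcg_at_k(ranking, qrels, qid, k)),
      infap = suppressWarnings(inf_ap(ranking, qrels, qid)),
      infndcg = suppressWarnings(inf_ndcg(ranking, qrels, qid)),
      judged = judged, unjudged = length(ranking) - judged,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  has_rel <- vapply(res$query_id, function(qid) {
    any(query_grades(qrels, qid) >= 1L)
  }, logical(1))
  metric_cols <- c("map", "p10_plus", "p10_minus", "ndcg10", "infap", "infndcg")
  means <- colMeans(res[has_rel, metric_cols, drop = FALSE], na.rm = TRUE)
  attr(res, "mean") <- means
  class(res) <- c("eval_result", "data.frame")
  if (!is.null(out)) {
    tab <- res
    mean_row <- data.frame(query_id = "mean", t(means), judged = NA,
                           unjudged = NA, stringsAsFactors = FALSE)
    names(mean_row) <- names(tab)
    utils::write.table(rbind(as.data.frame(tab), mean_row), out, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}
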