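#' Re-rank a retrieved list by entity overlap with the query
#'
#' Every document is re-scored s' = s_max * nD + sD, where sD is its base
#' retrieval score, s_max the score of the rank-1 document and nD the number
#' of unique entities it shares with the query ([shared_entity_count()]).
#' Documents missing from `n_shared` get nD = 0. Log-domain scorers can
#' produce non-positive sD, for which the formula loses its dominance intent
#' ("more shared entities ranks higher"); when any score is <= 0 the whole
#' list is shifted by a per-query constant (subtract the minimum, add 1),
#' which is order-preserving within every nD stratum, before applying the
#' formula.
#'
#' @param ranked [ranked_list()] of at most the retrieval depth (e.g. 10000).
#' @param n_shared Named integer vector doc_id -> nD; missing docs count 0.
#' @param final_k Documents to keep after re-ranking (default 1000).
#' @return [ranked_list()] of at most `final_k` documents, scored by the
#'   formula, ties broken by ascending doc_id.
#' @export
rerank <- function(ranked, n_shared = integer(0), final_k = 1000L) {
  if (final_k < 1) stop("final_k must be >= 1")
  if (nrow(ranked) == 0L) return(ranked)
  qid <- ranked$query_id[1L]
  s <- ranked$score
  if (min(s) <= 0) s <- s - min(s) + 1
  s_max <- s[which.max(s)]
  nd <- n_shared[ranked$doc_id]
  nd[is.na(nd)] <- 0
  new_score <- s_max * as.numeric(nd) + s
  rl <- ranked_list(qid, ranked$doc_id, new_score)
  if (nrow(rl) > final_k) {
    rl <- structure(rl[seq_len(final_k), ],
                    class = c("ranked_list", "data.frame"))
    rl$rank <- seq_len(final_k)
  }
  rl
}
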