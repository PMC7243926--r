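#' Normalize an entity surface form to its canonical dictionary key
#'
#' Lowercases, turns hyphens into spaces, inserts a space at letter-digit
#' boundaries, strips parenthesis/bracket characters (keeping their content)
#' and collapses whitespace. This single normalization realizes the
#' surface-similarity matching of the extractor: "bone morphogenetic
#' protein-2" and "bone morphogenetic protein 2" share one key, as do
#' "Gialpha(1)" and "Gi alpha(1)". Idempotent.
#'
#' @param x Character vector.
#' @return Canonical key string(s), same length as `x`.
#' @export
normalize_surface <- function(x) {
  if (is.null(x) || length(x) == 0L) return("")
  x[is.na(x)] <- ""
  y <- tolower(x)
  y <- gsub("[()\\[\\]]", " ", y, perl = TRUE)
  y <- gsub("-", " ", y, fixed = TRUE)
  y <- gsub("(?<=[[:alpha:]])(?=[0-9])", " ", y, perl = TRUE)
  y <- gsub("(?<=[0-9])(?=[[:alpha:]])", " ", y, perl = TRUE)
  y <- gsub("\\s+", " ", y)
  trimws(y)
}

# whitespace tokens of the raw text with 0-based half-open character spans
raw_tokens <- function(text) {
  m <- gregexpr("\\S+", text)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m) - 1L, end = as.integer(m + len - 1L),
             stringsAsFactors = FALSE)
}

# exact-key join; `on=` with a fresh i-table avoids the column/variable
# name capture of dictionary[list(key)]
dict_get <- function(dictionary, k) {
  i <- data.table::as.data.table(list(key = k))
  dictionary[i, on = "key", nomatch = NULL]
}

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), surface = character(),
             entity_id = character(), semantic_type = character(),
             source = character(), match_kind = character(),
             stringsAsFactors = FALSE)
}

#' Dictionary lookup of entity mentions
#'
#' Greedy longest-match-first scan of normalized token n-grams (n up to
#' `max_n`) against the dictionary keys; matched mentions never overlap. A
#' mention whose full n-gram equals a dictionary key is an exact match.
#'
#' @param text Raw unit text.
#' @param dictionary [entity_dictionary()].
#' @param max_n Longest entity n-gram considered (tokens of the raw text).
#' @return Mention data.frame (`start`, `end`, `surface`, `entity_id`,
#'   `semantic_type`, `source`, `match_kind`), spans 0-based half-open on the
#'   raw text.
#' @export
dict_lookup <- function(text, dictionary, max_n = 8L) {
  if (nrow(dictionary) == 0L) stop("dictionary is empty")
  toks <- raw_tokens(text)
  if (nrow(toks) == 0L) return(empty_mentions())
  norm <- normalize_surface(toks$token)
  keys <- dictionary$key
  single <- unique(keys[dictionary$n_tokens == 1L])
  multi_first <- unique(vapply(strsplit(unique(keys[dictionary$n_tokens > 1L]),
                                        " ", fixed = TRUE),
                               `[[`, character(1), 1L))
  out <- list()
  i <- 1L
  n_tok <- nrow(toks)
  while (i <= n_tok) {
    first_words <- strsplit(norm[i], " ", fixed = TRUE)[[1L]]
    fw <- if (length(first_words)) first_words[1L] else ""
    if (!nzchar(fw) || (!fw %in% multi_first && !norm[i] %in% single &&
                        !fw %in% single)) {
      i <- i + 1L
      next
    }
    matched <- FALSE
    for (n in seq(min(max_n, n_tok - i + 1L), 1L)) {
      span_norm <- norm[i:(i + n - 1L)]
      cand_key <- paste(span_norm[nzchar(span_norm)], collapse = " ")
      if (!nzchar(cand_key)) next
      hit <- dict_get(dictionary, cand_key)
      if (nrow(hit) > 0L) {
        hit <- hit[order(hit$source, hit$entity_id), ][1L, ]
        s <- toks$start[i]; e <- toks$end[i + n - 1L]
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e,
          surface = substr(text, s + 1L, e),
          entity_id = hit$entity_id, semantic_type = hit$semantic_type,
          source = "dictionary", match_kind = "exact",
          stringsAsFactors = FALSE)
        i <- i + n
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}

#' Detect acronym definitions in text
#'
#' Schwartz-Hearst-style pattern "long form (ACRONYM)": a parenthesized token
#' of 2-10 characters containing at least one uppercase letter and at least
#' one letter overall, whose characters align right-to-left against the
#' preceding words, the first acronym letter anchored at a word start.
#'
#' @param text Raw text.
#' @return data.frame `acronym`, `long_form` (one row per detected pair).
#' @export
detect_acronyms <- function(text) {
  out <- data.frame(acronym = character(), long_form = character(),
                    stringsAsFactors = FALSE)
  m <- gregexpr("\\(([^()]+)\\)", text)[[1L]]
  if (m[1L] == -1L) return(out)
  len <- attr(m, "match.length")
  for (j in seq_along(m)) {
    acro <- substring(text, m[j] + 1L, m[j] + len[j] - 2L)
    nc <- nchar(acro)
    if (nc < 2L || nc > 10L) next
    if (grepl("\\s", acro)) next
    if (!grepl("[A-Z]", acro)) next
    if (grepl("^[0-9]+$", acro)) next
    before <- trimws(substr(text, 1L, m[j] - 1L))
    if (!nzchar(before)) next
    words <- strsplit(before, "\\s+")[[1L]]
    n_letters <- nchar(gsub("[^[:alpha:]]", "", acro))
    take <- min(length(words), min(n_letters + 5L, n_letters * 2L))
    cand <- paste(utils::tail(words, take), collapse = " ")
    lf <- schwartz_hearst_long_form(acro, cand)
    if (!is.null(lf))
      out <- rbind(out, data.frame(acronym = acro, long_form = lf,
                                   stringsAsFactors = FALSE))
  }
  out
}

# right-to-left character alignment of the short form inside the candidate
# long form; the first character must align at a word start
schwartz_hearst_long_form <- function(short, cand) {
  s <- strsplit(tolower(short), "")[[1L]]
  l <- strsplit(tolower(cand), "")[[1L]]
  si <- length(s); li <- length(l)
  while (si > 0L) {
    ch <- s[si]
    if (!grepl("[[:alnum:]]", ch)) { si <- si - 1L; next }
    while (li > 0L &&
           (l[li] != ch || (si == 1L && li > 1L && grepl("[[:alnum:]]", l[li - 1L]))))
      li <- li - 1L
    if (li == 0L) return(NULL)
    si <- si - 1L
    li <- li - 1L
  }
  # expand left to the start of the word the first character matched in
  start <- li + 1L
  lf <- trimws(substr(cand, start, nchar(cand)))
  if (!nzchar(lf)) NULL else lf
}

#' Merge entity mentions from several annotators under priority rules
#'
#' For overlapping mentions of the gene/chemical/disease types the order is
#' pubtator > becas > dictionary; for all other semantic types becas >
#' dictionary (an external gene annotator is authoritative only for its
#' specialty types). Within dictionary hits an exact match beats a partial
#' one. Surviving mentions never overlap.
#'
#' @param mention_lists Named list `source -> mention data.frame` for one
#'   unit (names are informational; each row's `source` column is used).
#' @param priority Character vector, highest first, for the specialty types.
#' @return Merged, non-overlapping mention data.frame.
#' @export
merge_annotations <- function(mention_lists,
                              priority = c("pubtator", "becas", "dictionary")) {
  all_m <- do.call(rbind, c(list(empty_mentions()),
                            unname(mention_lists[!vapply(mention_lists, is.null,
                                                         logical(1))])))
  if (nrow(all_m) == 0L) return(empty_mentions())
  specialty <- c("GENE", "CHEM", "CHED", "DISO")
  rank_src <- function(src, type) {
    r <- match(src, priority)
    r[is.na(r)] <- length(priority) + 1L
    # outside its specialty types, pubtator carries no special authority
    r[!(type %in% specialty) & src == "pubtator"] <-
      match("becas", priority)
    r
  }
  pr <- rank_src(all_m$source, all_m$semantic_type)
  exact <- ifelse(all_m$match_kind == "exact", 0L, 1L)
  span <- all_m$end - all_m$start
  o <- order(pr, exact, -span, all_m$start, all_m$entity_id, method = "radix")
  all_m <- all_m[o, , drop = FALSE]
  kept <- logical(nrow(all_m))
  intervals <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(all_m))) {
    s <- all_m$start[i]; e <- all_m$end[i]
    if (nrow(intervals) == 0L ||
        all(e <= intervals[, 1] | s >= intervals[, 2])) {
      kept[i] <- TRUE
      intervals <- rbind(intervals, c(s, e))
    }
  }
  res <- all_m[kept, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Extract, normalize and merge entity mentions for one text unit
#'
#' Runs the dictionary lookup, lets detected acronyms inherit their long
#' form's dictionary entry within the unit, and merges with any external
#' annotations under [merge_annotations()] priorities.
#'
#' @param text Raw unit text.
#' @param dictionary [entity_dictionary()].
#' @param external Named list `source -> mention data.frame` (e.g. from
#'   [read_annotations()]), may be empty.
#' @param max_n Longest dictionary n-gram.
#' @return Merged mention data.frame.
#' @export
extract_entities <- function(text, dictionary, external = list(),
                             max_n = 8L) {
  dict_m <- dict_lookup(text, dictionary, max_n)
  acr <- detect_acronyms(text)
  if (nrow(acr) > 0L) {
    toks <- raw_tokens(text)
    for (j in seq_len(nrow(acr))) {
      hit <- dict_get(dictionary, normalize_surface(acr$long_form[j]))
      if (nrow(hit) == 0L) next
      hit <- hit[order(hit$source, hit$entity_id), ][1L, ]
      # every standalone occurrence of the acronym inherits the entry
      ak <- normalize_surface(acr$acronym[j])
      occ <- which(normalize_surface(toks$token) == ak)
      for (i in occ) {
        dict_m <- rbind(dict_m, data.frame(
          start = toks$start[i], end = toks$end[i], surface = toks$token[i],
          entity_id = hit$entity_id, semantic_type = hit$semantic_type,
          source = "dictionary", match_kind = "exact",
          stringsAsFactors = FALSE))
      }
    }
  }
  merge_annotations(c(list(dictionary = dict_m), external))
}

#' Count unique entities shared between query and document
#'
#' The currency of entity-overlap re-ranking: the size of the intersection of
#' the unique entity-id sets on the two sides.
#'
#' @param query_mentions,doc_mentions Mention data.frames.
#' @return Non-negative integer nD.
#' @export
shared_entity_count <- function(query_mentions, doc_mentions) {
  q <- unique(query_mentions$entity_id)
  d <- unique(doc_mentions$entity_id)
  length(intersect(q, d))
}
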