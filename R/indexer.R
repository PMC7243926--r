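#' Load or build a stopword list
#'
#' The base list is a standard frozen English stopword list shipped with the
#' package. In query mode the two domain additions "find" and "search" are
#' appended, since dataset-retrieval queries are phrased as search commands.
#'
#' @param query_mode Add "find" and "search".
#' @param extra Further terms to add.
#' @return Character vector of lowercase stop terms (class `stoplist`).
#' @export
make_stoplist <- function(query_mode = FALSE, extra = character(0)) {
  path <- system.file("extdata", "stopwords_en.txt", package = "posmrf")
  base <- readLines(path, warn = FALSE)
  out <- unique(c(base, if (query_mode) c("find", "search"), tolower(extra)))
  structure(out, class = c("stoplist", "character"))
}

#' Tokenize and normalize text
#'
#' Lowercases, splits on any non-alphanumeric character, and removes stoplist
#' terms while preserving order. By default intra-token hyphens are retained
#' ("t-cell" stays one token, as biomedical query terms require); with
#' `split_hyphens = TRUE` hyphens are treated as punctuation, the convention
#' used for the embedding-training corpus.
#'
#' @param text Character scalar (raw Unicode).
#' @param stoplist Terms to drop, or `NULL` to keep everything.
#' @param split_hyphens Treat `-` as punctuation.
#' @return Character vector of tokens (possibly empty).
#' @export
preprocess <- function(text, stoplist = NULL, split_hyphens = FALSE) {
  if (is.null(text) || length(text) == 0L || is.na(text)) return(character(0))
  x <- tolower(text)
  pat <- if (split_hyphens) "[^a-z0-9]+" else "[^a-z0-9-]+"
  x <- gsub(pat, " ", x)
  toks <- strsplit(trimws(x), " +", fixed = FALSE)[[1L]]
  if (!split_hyphens) {
    toks <- gsub("^-+|-+$", "", toks)   # edge hyphens are punctuation
  }
  toks <- toks[nzchar(toks)]
  if (!is.null(stoplist) && length(toks)) toks <- toks[!toks %in% stoplist]
  toks
}

#' Build the two-field positional inverted index
#'
#' Tokenizes title and description of every document (stopword removal before
#' positional indexing; positions are 0-based over the post-stopword token
#' sequence) and accumulates per-field postings plus the collection statistics
#' the ranking potentials need.
#'
#' @param docs List of [dataset_doc()] objects.
#' @param stoplist Stoplist used for both fields (document mode).
#' @return A `two_field_index`: list with `title` and `description`, each a
#'   `field_index` carrying `postings` (term -> doc_id -> integer positions),
#'   `doc_length`, `collection_length`, `collection_tf`, `df`, `doc_count`,
#'   `doc_ids`.
#' @export
build_index <- function(docs, stoplist = make_stoplist()) {
  ids <- vapply(docs, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_id: ", ids[duplicated(ids)][1L])
  fields <- list(
    title = lapply(docs, function(d) preprocess(d$title, stoplist)),
    description = lapply(docs, function(d) preprocess(d$description, stoplist)))
  out <- lapply(fields, function(tok_list) build_field_index(ids, tok_list))
  structure(out, class = "two_field_index")
}

build_field_index <- function(ids, tok_list) {
  lens <- lengths(tok_list)
  n_tok <- sum(lens)
  if (n_tok > 0L) {
    dt <- data.table::data.table(
      doc = rep(ids, lens),
      pos = unlist(lapply(lens, function(n) seq_len(n) - 1L)),
      term = unlist(tok_list))
    data.table::setkeyv(dt, c("term", "doc"))
    postings <- lapply(split(dt, by = "term", keep.by = FALSE),
                       function(sub) split(sub$pos, sub$doc))
    ctf <- vapply(postings, function(p) sum(lengths(p)), numeric(1))
    df <- vapply(postings, length, integer(1))
  } else {
    postings <- list(); ctf <- numeric(0); df <- integer(0)
  }
  doc_length <- as.numeric(lens); names(doc_length) <- ids
  structure(list(postings = postings, doc_length = doc_length,
                 collection_length = n_tok, collection_tf = ctf, df = df,
                 doc_count = length(ids), doc_ids = ids),
            class = "field_index")
}

#' @export
print.two_field_index <- function(x, ...) {
  cat("<two_field_index> ", x$title$doc_count, " docs; title: ",
      length(x$title$postings), " terms / ", x$title$collection_length,
      " tokens; description: ", length(x$description$postings), " terms / ",
      x$description$collection_length, " tokens\n", sep = "")
  invisible(x)
}

#' Serialize / load an index as JSON
#'
#' A versioned plain-text form so indexes can be built once and reused by the
#' command-line tools.
#'
#' @param index `two_field_index`.
#' @param path File path.
#' @return `path` (write) or the index (load).
#' @export
write_index <- function(index, path) {
  ser <- list(format = "posmrf-index", version = 1L,
              fields = lapply(unclass(index), function(fi) {
                # named atomic vectors lose names in JSON; ship them as maps
                list(postings = fi$postings, doc_length = as.list(fi$doc_length),
                     collection_length = fi$collection_length,
                     collection_tf = as.list(fi$collection_tf),
                     df = as.list(fi$df),
                     doc_count = fi$doc_count, doc_ids = fi$doc_ids)
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ser$format, "posmrf-index")) stop("not a posmrf index file")
  restore <- function(fi) {
    postings <- lapply(fi$postings, function(p) lapply(p, function(v)
      as.integer(unlist(v))))
    structure(list(postings = postings,
                   doc_length = unlist(fi$doc_length),
                   collection_length = as.numeric(fi$collection_length),
                   collection_tf = unlist(fi$collection_tf) %||% numeric(0),
                   df = unlist(fi$df) %||% integer(0),
                   doc_count = as.integer(fi$doc_count),
                   doc_ids = as.character(unlist(fi$doc_ids))),
              class = "field_index")
  }
  structure(lapply(ser$fields, restore), class = "two_field_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count ordered co-occurrences within a window
#'
#' Number of position pairs (p1, p2), p1 from `pos1`, p2 from `pos2`, with
#' `0 < p2 - p1 <= window` — the term-frequency surrogate for the sequential
#' (ordered) dependence potential.
#'
#' @param pos1,pos2 Sorted ascending integer position vectors of the two terms
#'   in one document field.
#' @param window Maximum gap (>= 1); `window = 1` counts exact bigrams.
#' @return Integer count.
#' @export
count_ordered <- function(pos1, pos2, window) {
  if (window < 1) stop("ordered window must be >= 1")
  if (length(pos1) == 0L || length(pos2) == 0L) return(0L)
  sum(findInterval(pos1 + window, pos2) - findInterval(pos1, pos2))
}

#' Count unordered co-occurrences within a window
#'
#' Number of position pairs with `|p1 - p2| < window`, either order — the
#' term-frequency surrogate for the full (unordered) dependence potential.
#'
#' @inheritParams count_ordered
#' @param window Window width (>= 2).
#' @return Integer count.
#' @export
count_unordered <- function(pos1, pos2, window) {
  if (window < 2) stop("unordered window must be >= 2")
  if (length(pos1) == 0L || length(pos2) == 0L) return(0L)
  sum(findInterval(pos1 + window - 1L, pos2) -
        findInterval(pos1 - window, pos2))
}
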