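#' @useDynLib posmrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

#' Construct a dataset-metadata document
#'
#' A `dataset_doc` carries the raw (un-preprocessed) `title` and `description`
#' of one metadata record plus its opaque identifier.
#'
#' @param doc_id Non-empty identifier, unique within a collection.
#' @param title,description Free text; `NULL`/`NA` become the empty string.
#' @return A `dataset_doc` list with fields `doc_id`, `title`, `description`.
#' @export
dataset_doc <- function(doc_id, title = "", description = "") {
  if (is.null(doc_id) || is.na(doc_id) || !nzchar(doc_id))
    stop("doc_id must be a non-empty string")
  norm <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x)) "" else as.character(x)
  }
  structure(list(doc_id = as.character(doc_id),
                 title = norm(title), description = norm(description)),
            class = "dataset_doc")
}

#' Default field map for dataset JSON records
#'
#' JSON paths are dot-delimited strings pointing at the identifier, title and
#' description inside each record.
#'
#' @param id,title,description Dot-delimited JSON paths.
#' @return A named list usable as `field_map` in [read_datasets()].
#' @export
field_map <- function(id = "_id", title = "metadata.title",
                      description = "metadata.description") {
  list(id = id, title = title, description = description)
}

json_path_get <- function(record, path) {
  for (key in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(record) || is.null(record[[key]])) return(NULL)
    record <- record[[key]]
  }
  record
}

#' Read dataset-metadata records from JSON
#'
#' Accepts a JSON-lines file (one record per line), a file containing a JSON
#' array of records, or a directory of per-record `.json` files. Records whose
#' id path is missing are skipped with a warning; missing title/description
#' become empty strings.
#'
#' @param path File or directory.
#' @param fmap Field map from [field_map()].
#' @return List of [dataset_doc()] objects; attribute `warning_count` holds the
#'   number of skipped/malformed records.
#' @export
read_datasets <- function(path, fmap = field_map()) {
  if (!file.exists(path)) stop("cannot read datasets: no such path: ", path)
  records <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    for (f in files) {
      rec <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE),
                      error = function(e) NULL)
      records[[length(records) + 1L]] <- if (is.null(rec)) NA else rec
    }
  } else {
    txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
    joined <- paste(txt, collapse = "\n")
    first <- sub("^\\s+", "", joined)
    if (startsWith(first, "[")) {
      arr <- jsonlite::fromJSON(joined, simplifyVector = FALSE)
      records <- arr
    } else {
      for (line in txt) {
        if (!nzchar(trimws(line))) next
        rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                        error = function(e) NULL)
        records[[length(records) + 1L]] <- if (is.null(rec)) NA else rec
      }
    }
  }
  docs <- list()
  seen <- new.env(parent = emptyenv())
  n_warn <- 0L
  for (rec in records) {
    if (!is.list(rec)) { n_warn <- n_warn + 1L; next }  # malformed JSON
    id <- json_path_get(rec, fmap$id)
    if (is.null(id) || !nzchar(as.character(id)[1L])) {
      n_warn <- n_warn + 1L
      next
    }
    id <- as.character(id)[1L]
    if (!is.null(seen[[id]])) { n_warn <- n_warn + 1L; next }
    assign(id, TRUE, envir = seen)
    ti <- json_path_get(rec, fmap$title)
    de <- json_path_get(rec, fmap$description)
    docs[[length(docs) + 1L]] <- dataset_doc(
      id,
      if (is.null(ti)) "" else as.character(ti)[1L],
      if (is.null(de)) "" else as.character(de)[1L])
  }
  if (n_warn > 0L)
    warning(n_warn, " record(s) skipped (malformed or missing/duplicate id)")
  attr(docs, "warning_count") <- n_warn
  docs
}

#' Read queries, one per line
#'
#' Lines are `query_id<TAB>text` (or first-whitespace-delimited). Empty lines
#' are ignored.
#'
#' @param path Query file.
#' @return data.frame with columns `query_id`, `text`.
#' @export
read_queries <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  m <- regexpr("\\s+", lines)
  if (any(m < 0)) stop("query line without text: ", lines[which(m < 0)[1L]])
  qid <- substr(lines, 1L, m - 1L)
  txt <- trimws(substr(lines, m + attr(m, "match.length"), nchar(lines)))
  if (anyDuplicated(qid)) stop("duplicate query_id in ", path)
  if (any(!nzchar(txt))) stop("empty query text in ", path)
  data.frame(query_id = qid, text = txt, stringsAsFactors = FALSE)
}

#' Read graded relevance judgments (qrels)
#'
#' Whitespace-delimited lines `qid iter docid grade`. With `stratified = TRUE`
#' the second column is read as a stratum label instead of being ignored.
#' Grades must be 0 (not relevant), 1 (partially relevant) or 2 (relevant).
#' Duplicate (qid, docid) pairs: last one wins, with a warning.
#'
#' @param path qrels file.
#' @param stratified Interpret column 2 as a stratum label.
#' @return A `sampled_qrels` object: data.table `judgments` with columns
#'   `query_id`, `doc_id`, `grade` and (if stratified) `stratum`, plus a
#'   `stratum_meta` data.table (`query_id`, `stratum`, `pool_size`,
#'   `sample_size`), empty unless set by [sample_qrels()] or manually.
#' @export
read_qrels <- function(path, stratified = FALSE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(sampled_qrels(empty_judgments(stratified)))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed qrels line ", bad[1L], ": ", lines[bad[1L]])
  mat <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  grade <- suppressWarnings(as.integer(mat[, 4L]))
  bad <- which(is.na(grade) | !(grade %in% 0:2))
  if (length(bad))
    stop("grade outside {0,1,2} at qrels line ", bad[1L], ": ", lines[bad[1L]])
  dt <- data.table::data.table(query_id = mat[, 1L], doc_id = mat[, 3L],
                               grade = grade)
  if (stratified) dt[, "stratum" := mat[, 2L]]
  ndup <- sum(duplicated(dt, by = c("query_id", "doc_id")))
  if (ndup > 0L) {
    warning(ndup, " duplicate (query, doc) judgment(s); last wins")
    dt <- dt[!duplicated(dt, by = c("query_id", "doc_id"), fromLast = TRUE)]
  }
  sampled_qrels(dt)
}

empty_judgments <- function(stratified = FALSE) {
  dt <- data.table::data.table(query_id = character(), doc_id = character(),
                               grade = integer())
  if (stratified) dt[, "stratum" := character()]
  dt
}

#' Construct a sampled_qrels object
#'
#' @param judgments data.table/data.frame with `query_id`, `doc_id`, `grade`
#'   and optionally `stratum`.
#' @param stratum_meta Optional data.frame with `query_id`, `stratum`,
#'   `pool_size`, `sample_size`. When absent, judgments are treated as the
#'   complete pool.
#' @return `sampled_qrels` object.
#' @export
sampled_qrels <- function(judgments, stratum_meta = NULL) {
  dt <- data.table::as.data.table(judgments)
  if (nrow(dt) && !all(dt$grade %in% 0:2))
    stop("grades must be in {0,1,2}")
  if (!is.null(stratum_meta)) {
    sm <- data.table::as.data.table(stratum_meta)
    if (any(sm$sample_size > sm$pool_size))
      stop("sample_size exceeds pool_size in stratum_meta")
  } else {
    sm <- data.table::data.table(query_id = character(), stratum = character(),
                                 pool_size = integer(), sample_size = integer())
  }
  structure(list(judgments = dt, stratum_meta = sm), class = "sampled_qrels")
}

#' @export
print.sampled_qrels <- function(x, ...) {
  cat("<sampled_qrels> ", nrow(x$judgments), " judgments, ",
      length(unique(x$judgments$query_id)), " queries, ",
      if (nrow(x$stratum_meta)) "stratified sampling metadata present"
      else "complete-judgment (no sampling metadata)", "\n", sep = "")
  invisible(x)
}

#' Construct a per-query ranked list
#'
#' @param query_id Query identifier.
#' @param doc_id Character vector of document ids (no duplicates).
#' @param score Numeric scores, non-increasing after the internal sort
#'   (ties broken by ascending doc_id).
#' @return `ranked_list` object: data.frame `query_id`, `doc_id`, `rank`,
#'   `score`.
#' @export
ranked_list <- function(query_id, doc_id, score) {
  stopifnot(length(doc_id) == length(score))
  if (anyDuplicated(doc_id)) stop("duplicate doc_id in ranked list")
  doc_id <- unname(doc_id)
  score <- unname(score)
  o <- order(-score, doc_id, method = "radix")
  df <- data.frame(query_id = rep(query_id, length(doc_id)),
                   doc_id = doc_id[o], rank = seq_along(o),
                   score = score[o], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("ranked_list", "data.frame"))
}

#' Write ranked lists in TREC run format
#'
#' Six columns `qid Q0 docid rank score tag`; scores are printed with six fixed
#' decimal digits; at most 1000 lines per query (extra entries are truncated
#' with a warning); score ties are broken by ascending doc_id.
#'
#' @param lists A `ranked_list` or a list of them (one per query).
#' @param tag Run label.
#' @param path Output file.
#' @param max_per_query Per-query line cap.
#' @return `path`, invisibly.
#' @export
write_run <- function(lists, tag, path, max_per_query = 1000L) {
  if (inherits(lists, "ranked_list")) lists <- list(lists)
  out <- character(0)
  for (rl in lists) {
    if (nrow(rl) == 0L) next
    if (nrow(rl) > max_per_query) {
      warning("query ", rl$query_id[1L], ": ", nrow(rl), " entries truncated to ",
              max_per_query)
      rl <- rl[seq_len(max_per_query), ]
    }
    out <- c(out, sprintf("%s Q0 %s %d %.6f %s", rl$query_id, rl$doc_id,
                          seq_len(nrow(rl)), rl$score, tag))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a TREC run file
#'
#' @param path Run file written by [write_run()] or any TREC-format run.
#' @return data.frame `query_id`, `doc_id`, `rank`, `score`, `tag`, ordered by
#'   query then rank.
#' @export
read_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(query_id = character(), doc_id = character(),
                      rank = integer(), score = numeric(), tag = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 6L)) stop("malformed run line in ", path)
  mat <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  df <- data.frame(query_id = mat[, 1L], doc_id = mat[, 3L],
                   rank = as.integer(mat[, 4L]), score = as.numeric(mat[, 5L]),
                   tag = mat[, 6L], stringsAsFactors = FALSE)
  df[order(df$query_id, df$rank), , drop = FALSE]
}

#' Read entity annotations from TSV
#'
#' Lines `unit_id<TAB>start<TAB>end<TAB>surface<TAB>entity_id<TAB>semantic_type<TAB>source`.
#' Character spans are 0-based, half-open, on the raw (un-preprocessed) text.
#' Sources are preserved; merging across sources happens in
#' [merge_annotations()].
#'
#' @param path TSV file; a missing path yields an empty annotation map.
#' @return Named list: unit_id -> data.frame of mentions (`start`, `end`,
#'   `surface`, `entity_id`, `semantic_type`, `source`, `match_kind`).
#' @export
read_annotations <- function(path) {
  if (is.null(path) || !file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 7L)) stop("annotation line must have 7 TSV fields")
  mat <- matrix(unlist(parts), ncol = 7L, byrow = TRUE)
  start <- as.integer(mat[, 2L]); end <- as.integer(mat[, 3L])
  bad <- which(end <= start)
  if (length(bad))
    stop("annotation with end <= start at line ", bad[1L], ": ", lines[bad[1L]])
  df <- data.frame(unit_id = mat[, 1L], start = start, end = end,
                   surface = mat[, 4L], entity_id = mat[, 5L],
                   semantic_type = mat[, 6L], source = mat[, 7L],
                   match_kind = "exact", stringsAsFactors = FALSE)
  split(df[, -1L], df$unit_id)
}

#' Write entity mentions as annotation TSV
#'
#' @param mentions Named list of mention data.frames as from
#'   [read_annotations()] or [extract_entities()].
#' @param path Output file.
#' @export
write_annotations <- function(mentions, path) {
  rows <- character(0)
  for (uid in names(mentions)) {
    m <- mentions[[uid]]
    if (is.null(m) || nrow(m) == 0L) next
    rows <- c(rows, sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s", uid, m$start, m$end,
                            m$surface, m$entity_id, m$semantic_type, m$source))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read an entity dictionary from TSV
#'
#' Lines `surface<TAB>entity_id<TAB>semantic_type<TAB>source`. Surfaces are
#' normalized with [normalize_surface()] on load so lookups operate on
#' canonical keys; one entry per (key, source) is kept (first wins).
#'
#' @param path TSV file.
#' @return `entity_dictionary`: data.table keyed by normalized surface, with
#'   columns `key`, `entity_id`, `semantic_type`, `source`, `n_tokens`.
#' @export
read_entity_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop("dictionary line must have 4 TSV fields")
  mat <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  entity_dictionary(surface = mat[, 1L], entity_id = mat[, 2L],
                    semantic_type = mat[, 3L], source = mat[, 4L])
}

#' Build an entity dictionary from vectors
#'
#' @param surface,entity_id,semantic_type,source Parallel character vectors.
#' @return `entity_dictionary` object (see [read_entity_dictionary()]).
#' @export
entity_dictionary <- function(surface, entity_id, semantic_type, source) {
  types_ok <- c("GENE", "CHEM", "DISO", "PROC", "ANAT", "SPEC", "PATH",
                "CELLCOMP", "BIOPROC", "OTHER", "CHED")
  semantic_type <- toupper(semantic_type)
  semantic_type[!semantic_type %in% types_ok] <- "OTHER"
  key <- normalize_surface(surface)
  # not data.table(key = ...): that would be its `key` argument
  dt <- data.table::as.data.table(list(key = key, entity_id = entity_id,
                                       semantic_type = semantic_type,
                                       source = source))
  dt <- dt[nzchar(key)]
  dt <- dt[!duplicated(dt, by = c("key", "source"))]
  dt[, "n_tokens" := lengths(strsplit(key, " ", fixed = TRUE))]
  data.table::setkeyv(dt, "key")
  structure(dt, class = c("entity_dictionary", class(dt)))
}
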