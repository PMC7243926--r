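test_that("normalize_surface applies the documented rules and is idempotent", {
  expect_identical(normalize_surface("bone morphogenetic protein-2"),
                   "bone morphogenetic protein 2")
  expect_identical(normalize_surface("Gialpha(1)"), "gialpha 1")
  expect_identical(normalize_surface("Gi alpha(2)"), "gi alpha 2")
  expect_identical(normalize_surface(""), "")
  cases <- c("BRCA1", "IL-2  receptor", "(nested) Text", "a1b2c3")
  for (x in cases) {
    expect_identical(normalize_surface(normalize_surface(x)),
                     normalize_surface(x))
  }
})

fixture_dict <- function() {
  entity_dictionary(
    surface = c("stage I breast cancer", "breast cancer",
                "bone morphogenetic protein 2", "multiple sclerosis",
                "gialpha 1", "gi alpha 2", "estrogen"),
    entity_id = c("mesh:D1", "mesh:D2", "entrez:650", "mesh:D9",
                  "up:G1", "up:G2", "mesh:C1"),
    semantic_type = c("DISO", "DISO", "GENE", "DISO", "GENE", "GENE", "CHEM"),
    source = "fixture")
}

test_that("dict_lookup takes the longest match and never overlaps", {
  d <- fixture_dict()
  m <- dict_lookup("stage I breast cancer", d)
  expect_identical(nrow(m), 1L)
  expect_identical(m$entity_id, "mesh:D1")     # 4-token match beats 2-token
  expect_identical(m$semantic_type, "DISO")
  expect_identical(nrow(dict_lookup("no entities here at all", d)), 0L)
  # surface variants resolve through normalization
  m2 <- dict_lookup("both Gialpha(1) and Gi alpha(2) were measured", d)
  expect_setequal(m2$entity_id, c("up:G1", "up:G2"))
  # spans index the raw text, 0-based half-open
  expect_identical(substr("both Gialpha(1) and", m2$start[1] + 1, m2$end[1]),
                   "Gialpha(1)")
})

test_that("dict_lookup output is invariant to dictionary entry order and fuzz-safe", {
  d <- fixture_dict()
  set.seed(17)
  perm <- d[sample(nrow(d)), ]
  d2 <- entity_dictionary(perm$key, perm$entity_id, perm$semantic_type,
                          perm$source)
  words <- c("stage", "I", "breast", "cancer", "estrogen", "protein", "and",
             "bone", "morphogenetic", "filler")
  for (i in 1:30) {
    txt <- paste(sample(words, sample(3:12, 1), replace = TRUE), collapse = " ")
    m1 <- dict_lookup(txt, d)
    m2 <- dict_lookup(txt, d2)
    expect_identical(m1, m2)
    if (nrow(m1) > 1) {
      o <- order(m1$start)
      expect_true(all(m1$end[o][-nrow(m1)] <= m1$start[o][-1]))
    }
  }
})

test_that("detect_acronyms finds definitional pairs and rejects non-acronyms", {
  a1 <- detect_acronyms("patients with multiple sclerosis (MS) were enrolled")
  expect_identical(a1$acronym, "MS")
  expect_identical(a1$long_form, "multiple sclerosis")
  a2 <- detect_acronyms("interleukin-1β (IL-1β) signaling")
  expect_identical(a2$acronym, "IL-1β")
  expect_identical(a2$long_form, "interleukin-1β")
  expect_identical(nrow(detect_acronyms("as shown earlier (1997) in mice")), 0L)
  expect_identical(nrow(detect_acronyms("no parens at all")), 0L)
})

test_that("acronyms inherit the long form's dictionary entry within a unit", {
  d <- fixture_dict()
  m <- extract_entities("multiple sclerosis (MS) is studied. MS progresses.", d)
  ms_rows <- m[m$entity_id == "mesh:D9", ]
  expect_gte(nrow(ms_rows), 2L)   # long form + standalone acronym occurrence
})

test_that("merge_annotations applies the source priority rules", {
  dict_m <- data.frame(start = 0L, end = 5L, surface = "BRCA1",
                       entity_id = "dict:brca1", semantic_type = "GENE",
                       source = "dictionary", match_kind = "exact",
                       stringsAsFactors = FALSE)
  pub_m <- data.frame(start = 0L, end = 5L, surface = "BRCA1",
                      entity_id = "ncbi:672", semantic_type = "GENE",
                      source = "pubtator", match_kind = "exact",
                      stringsAsFactors = FALSE)
  out <- merge_annotations(list(dictionary = dict_m, pubtator = pub_m))
  expect_identical(out$entity_id, "ncbi:672")  # pubtator wins on GENE

  # outside the specialty types, becas outranks pubtator does not apply:
  # becas beats dictionary
  bec <- pub_m; bec$source <- "becas"; bec$semantic_type <- "PROC"
  dic <- dict_m; dic$semantic_type <- "PROC"
  out2 <- merge_annotations(list(dictionary = dic, becas = bec))
  expect_identical(out2$source, "becas")

  # non-conflicting mention survives
  far <- dict_m; far$start <- 50L; far$end <- 55L
  out3 <- merge_annotations(list(dictionary = rbind(dict_m, far),
                                 pubtator = pub_m))
  expect_identical(nrow(out3), 2L)

  # exact beats partial on the same span
  part <- dict_m; part$match_kind <- "partial"; part$entity_id <- "dict:part"
  out4 <- merge_annotations(list(a = part, b = dict_m))
  expect_identical(out4$entity_id, "dict:brca1")
})

test_that("merged mentions never overlap and never exceed the input count", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    starts <- sample(0:30, n, replace = TRUE)
    ments <- data.frame(
      start = starts, end = starts + sample(1:6, n, replace = TRUE),
      surface = sprintf("s%d", 1:n),
      entity_id = sprintf("id%d", sample(3, n, replace = TRUE)),
      semantic_type = sample(c("GENE", "DISO", "PROC"), n, replace = TRUE),
      source = sample(c("pubtator", "becas", "dictionary"), n, replace = TRUE),
      match_kind = sample(c("exact", "partial"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    out <- merge_annotations(list(x = ments))
    expect_lte(nrow(out), nrow(ments))
    if (nrow(out) > 1) {
      o <- order(out$start)
      expect_true(all(out$end[o][-nrow(out)] <= out$start[o][-1]))
    }
  }
})

test_that("shared_entity_count intersects unique entity ids", {
  qm <- data.frame(entity_id = c("ncbi:672", "mesh:D001943"))
  dm <- data.frame(entity_id = rep("ncbi:672", 5))
  expect_identical(shared_entity_count(qm, dm), 1L)
  expect_identical(shared_entity_count(qm, data.frame(entity_id = "x")), 0L)
  expect_identical(shared_entity_count(qm, qm), 2L)
})
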