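simple_qrels <- function(...) {
  df <- data.frame(...)
  df$query_id <- "q1"
  sampled_qrels(df[, c("query_id", "doc_id", "grade")])
}

test_that("average_precision matches hand computations", {
  qr <- simple_qrels(doc_id = c("a", "b"), grade = c(2L, 1L))
  expect_equal(average_precision(c("a", "b", "c"), qr, "q1"), 1.0)
  # relevant at ranks 2 and 4, R = 2 -> (1/2 + 2/4)/2 = 0.5
  expect_equal(average_precision(c("x", "a", "y", "b"), qr, "q1"), 0.5)
  expect_equal(average_precision(c("x", "y"), qr, "q1"), 0)
  qr0 <- simple_qrels(doc_id = "a", grade = 0L)
  expect_warning(v <- average_precision("a", qr0, "q1"), "no relevant")
  expect_true(is.na(v))
  # threshold 2 drops the partially relevant doc from R
  expect_equal(average_precision(c("a", "b"), qr, "q1", rel_threshold = 2L), 1.0)
})

test_that("precision_at_k counts with and without partials", {
  qr <- simple_qrels(doc_id = c("a", "b"), grade = c(2L, 1L))
  ranking <- c("a", "b", sprintf("x%d", 1:8))
  expect_equal(precision_at_k(ranking, qr, "q1", 10, TRUE), 0.2)
  expect_equal(precision_at_k(ranking, qr, "q1", 10, FALSE), 0.1)
  expect_equal(precision_at_k(character(0), qr, "q1", 10), 0)
})

test_that("ndcg_at_k matches the hand-computed two-doc case", {
  qr <- simple_qrels(doc_id = c("a", "b"), grade = c(2L, 0L))
  expect_equal(ndcg_at_k(c("b", "a"), qr, "q1", k = 2),
               (2 / log2(3)) / (2 / log2(2)), tolerance = 1e-12)
  qr2 <- simple_qrels(doc_id = c("a", "b", "c"), grade = c(2L, 1L, 0L))
  expect_equal(ndcg_at_k(c("a", "b", "c"), qr2, "q1"), 1.0)
  qr0 <- simple_qrels(doc_id = "a", grade = 0L)
  expect_warning(v <- ndcg_at_k("a", qr0, "q1"), "ideal DCG 0")
  expect_true(is.na(v))
})

test_that("classical metrics equal their definitional oracles on 200 fuzzed cases", {
  set.seed(2024)
  for (i in 1:200) {
    case <- random_eval_case()
    grades <- with(case$qrels$judgments, setNames(grade, doc_id))
    ap <- suppressWarnings(average_precision(case$ranking, case$qrels, "q1"))
    expect_equal(ap, oracle_ap(case$ranking, grades), tolerance = 1e-9)
    expect_equal(precision_at_k(case$ranking, case$qrels, "q1", 10, TRUE),
                 oracle_p_at_k(case$ranking, grades, 10, 1), tolerance = 1e-9)
    expect_equal(precision_at_k(case$ranking, case$qrels, "q1", 10, FALSE),
                 oracle_p_at_k(case$ranking, grades, 10, 2), tolerance = 1e-9)
    nd <- suppressWarnings(ndcg_at_k(case$ranking, case$qrels, "q1", 10))
    expect_equal(nd, oracle_ndcg(case$ranking, grades, 10), tolerance = 1e-9)
    # set-containment invariant
    expect_gte(precision_at_k(case$ranking, case$qrels, "q1", 10, TRUE),
               precision_at_k(case$ranking, case$qrels, "q1", 10, FALSE))
  }
})

test_that("inferred measures reduce exactly to their classical forms", {
  set.seed(31)
  for (i in 1:50) {
    case <- random_eval_case()
    ap <- suppressWarnings(average_precision(case$ranking, case$qrels, "q1"))
    iap <- suppressWarnings(inf_ap(case$ranking, case$qrels, "q1"))
    if (!is.na(ap)) expect_lt(abs(iap - ap), 1e-6)
    k_full <- max(length(case$ranking), nrow(case$qrels$judgments))
    nd <- suppressWarnings(ndcg_at_k(case$ranking, case$qrels, "q1",
                                     k = k_full))
    ind <- suppressWarnings(inf_ndcg(case$ranking, case$qrels, "q1"))
    if (!is.na(nd)) expect_lt(abs(ind - nd), 1e-6)
  }
})

test_that("a sampled relevant doc at rank 1 contributes exactly 1", {
  qr <- simple_qrels(doc_id = "a", grade = 2L)
  expect_equal(inf_ap(c("a"), qr, "q1"), 1.0, tolerance = 1e-9)
})

test_that("a sample with no relevant docs yields 0 with a warning", {
  qr <- simple_qrels(doc_id = c("a", "b"), grade = c(0L, 0L))
  expect_warning(v <- inf_ap(c("a", "b"), qr, "q1"), "no relevant")
  expect_equal(v, 0)
  expect_warning(v2 <- inf_ndcg(c("a", "b"), qr, "q1"), "no relevant")
  expect_equal(v2, 0)
})

test_that("inferred measures are approximately unbiased under 50% sampling", {
  # scaled-down sanity check (the acceptance suite runs the full 500 draws)
  set.seed(88)
  n <- 150
  docs <- sprintf("m%03d", 1:n)
  grades <- sample(0:2, n, replace = TRUE, prob = c(0.75, 0.13, 0.12))
  full <- sampled_qrels(data.frame(query_id = "q1", doc_id = docs,
                                   grade = grades))
  ranking <- sample(docs)
  truth_ap <- average_precision(ranking, full, "q1")
  truth_ndcg <- ndcg_at_k(ranking, full, "q1", k = n)
  draws <- sapply(1:120, function(s) {
    sq <- suppressWarnings(sample_qrels(full, 0.5, seed = s))
    c(suppressWarnings(inf_ap(ranking, sq, "q1")),
      suppressWarnings(inf_ndcg(ranking, sq, "q1")))
  })
  expect_lt(abs(mean(draws[1, ]) - truth_ap), 0.03)
  expect_lt(abs(mean(draws[2, ]) - truth_ndcg), 0.04)
})

test_that("evaluate_run produces the six measures and is reproducible", {
  qr <- sampled_qrels(data.frame(
    query_id = rep(c("q1", "q2"), each = 3),
    doc_id = rep(c("a", "b", "c"), 2),
    grade = c(2L, 1L, 0L, 2L, 0L, 0L)))
  runs <- list(ranked_list("q1", c("a", "b", "c"), c(3, 2, 1)),
               ranked_list("q2", c("b", "a", "c"), c(3, 2, 1)))
  res <- evaluate_run(runs, qr)
  expect_identical(res$query_id, c("q1", "q2"))
  expect_equal(res$ndcg10[1], 1.0)            # qrels-ideal ordering
  expect_equal(res$map[1], 1.0)
  expect_equal(res$map[2], 0.5)               # relevant at rank 2
  expect_identical(evaluate_run(runs, qr), res)
  m <- attr(res, "mean")
  expect_true(all(m[c("map", "ndcg10", "infap", "infndcg")] >= 0 &
                    m[c("map", "ndcg10", "infap", "infndcg")] <= 1))
  # TSV emission
  f <- withr::local_tempfile(fileext = ".tsv")
  evaluate_run(runs, qr, out = f)
  tab <- read.delim(f)
  expect_identical(tab$query_id, c("q1", "q2", "mean"))
  expect_error(evaluate_run(list(ranked_list("zz", "a", 1)), qr), "share no")
})

test_that("evaluation is invariant to qrels file order", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  lines <- c("q1 0 a 2", "q1 0 b 1", "q1 0 c 0")
  writeLines(lines, f1)
  writeLines(rev(lines), f2)
  runs <- list(ranked_list("q1", c("c", "a", "b"), c(3, 2, 1)))
  expect_identical(evaluate_run(runs, read_qrels(f1)),
                   evaluate_run(runs, read_qrels(f2)))
})
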