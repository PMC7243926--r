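test_that("the reference tagger reproduces the documented taggings", {
  expect_identical(pos_tag("search"), "NN")   # bare imperative, not VB
  expect_identical(pos_tag("obese"), "JJ")
  expect_identical(pos_tag(c("data", "related", "types")),
                   c("NNS", "VBN", "NNS"))
  expect_length(pos_tag("glycolysis"), 1L)
  expect_error(pos_tag(character(0)), "non-empty")
  # pluggable tagger contract
  expect_identical(pos_tag(c("a", "b"), tagger = function(x) rep("XX", length(x))),
                   c("XX", "XX"))
  expect_error(pos_tag(c("a", "b"), tagger = function(x) "XX"), "tagger returned")
})

test_that("lambda_for maps tag classes to the optimized constants", {
  expect_equal(lambda_for("NN"), 0.5970)
  expect_equal(lambda_for("NNS"), 0.2265)
  expect_equal(lambda_for("VBN"), 0.3065)
  expect_equal(lambda_for("VBD"), 0.2260)
  expect_equal(lambda_for("JJ"), 0.3730)
  expect_equal(lambda_for("RB"), 0.1040)
  expect_equal(lambda_for("NNP"), 0.8930)
  expect_equal(lambda_for(c("CD", "VBG", "IN")), c(0, 0, 0))  # OTHER
})

# fixture giving exact round statistics: term "tt" occurs twice in a 10-token
# d1 and nowhere else; 190 filler tokens in d2 -> P(tt|C) = 2/200 = 0.01
mu_fixture <- function() {
  filler <- paste(rep(sprintf("f%02d", 1:19), length.out = 190), collapse = " ")
  build_index(list(
    dataset_doc("d1", paste("tt tt", paste(sprintf("x%d", 1:8), collapse = " ")), ""),
    dataset_doc("d2", filler, "")))
}

test_that("potential_F matches the hand-computed Dirichlet value", {
  idx <- mu_fixture()
  expect_equal(potential_F("tt", "d1", idx$title, mu = 10), log(0.105),
               tolerance = 1e-12)
  # monotonicity in tf: absent term scores lower in the same doc
  p_absent <- potential_F("f01", "d1", idx$title, mu = 10)
  expect_lt(p_absent, potential_F("tt", "d1", idx$title, mu = 10))
  # mu -> Inf limit approaches log P(term|C)
  expect_equal(potential_F("tt", "d2", idx$title, mu = 1e9), log(0.01),
               tolerance = 1e-4)
  # out-of-collection floor is finite
  expect_true(is.finite(potential_F("zzz", "d1", idx$title)))
})

test_that("ordered potential rewards adjacency over distance", {
  pad <- paste(sprintf("p%d", 1:10), collapse = " ")
  idx <- build_index(list(
    dataset_doc("da", paste("alpha beta", pad), ""),
    dataset_doc("db", paste("alpha", pad, "beta"), "")))
  cfg <- clique_config()
  expect_gt(potential_O("alpha", "beta", "da", idx$title, cfg),
            potential_O("alpha", "beta", "db", idx$title, cfg))
  # never co-occurring pair hits the finite floor
  expect_true(is.finite(potential_U("alpha", "p9", "db", idx$title, cfg)))
})

test_that("reduction chain: POS-MRF(lambda=1) == MRF; MRF(theta=(1,0,0)) == QL", {
  set.seed(5)
  docs <- random_docs(40)
  idx <- build_index(docs)
  vocab <- names(idx$title$postings)
  for (i in 1:5) {
    toks <- sample(vocab, 3)
    q <- tagged_query(toks, sprintf("q%d", i))
    r_pos <- retrieve(idx, q, "posmrf", k = 50, weights = uniform_pos_weights())
    r_mrf <- retrieve(idx, q, "mrf", k = 50)
    expect_identical(r_pos$doc_id, r_mrf$doc_id)
    expect_equal(r_pos$score, r_mrf$score, tolerance = 1e-12)
    cfg_f <- clique_config(theta_F = 1, theta_O = 0, theta_U = 0)
    r_f <- retrieve(idx, q, "mrf", k = 50, config = cfg_f)
    r_ql <- retrieve(idx, q, "ql", k = 50)
    expect_identical(r_f$doc_id, r_ql$doc_id)
    expect_equal(r_f$score, r_ql$score, tolerance = 1e-12)
  }
})

test_that("single-term query reduces to theta_F * potential_F", {
  idx <- mu_fixture()
  cfg <- clique_config(field_weights = c(1, 0))
  q <- tagged_query("tt", "q1", tokenized = TRUE)
  expect_equal(score_mrf(q, "d1", idx, cfg),
               0.8 * potential_F("tt", "d1", idx$title, cfg$dirichlet_mu),
               tolerance = 1e-12)
})

test_that("an all-OTHER-tag query scores 0 under POS-MRF", {
  idx <- mu_fixture()
  q <- tagged_query("tt", "q1", tagger = function(x) rep("VBG", length(x)),
                    tokenized = TRUE)
  expect_equal(score_posmrf(q, "d1", idx), 0)
})

test_that("score_mrf equals the brute-force clique-sum oracle on 3-term queries", {
  set.seed(13)
  vocab <- sprintf("w%02d", 1:12)
  for (rep in 1:5) {
    toks <- lapply(1:6, function(i) sample(vocab, sample(5:20, 1), replace = TRUE))
    names(toks) <- sprintf("d%d", 1:6)
    docs <- lapply(names(toks), function(d)
      dataset_doc(d, paste(toks[[d]], collapse = " "), ""))
    idx <- build_index(docs)
    qt <- sample(vocab, 3)
    q <- tagged_query(qt, "q")
    cfg <- clique_config(field_weights = c(1, 0))
    for (d in names(toks)) {
      expect_equal(score_mrf(q, d, idx, cfg),
                   oracle_mrf_score(qt, toks, d), tolerance = 1e-10)
    }
    # POS-MRF against the same oracle with per-term lambdas
    lam <- lambda_for(pos_tag(qt))
    for (d in names(toks)[1:2]) {
      expect_equal(score_posmrf(q, d, idx, cfg),
                   oracle_mrf_score(qt, toks, d, lambda = lam),
                   tolerance = 1e-10)
    }
  }
})

test_that("adding a matching bigram never decreases the MRF score", {
  set.seed(21)
  pad <- function(n) paste(sample(sprintf("z%d", 1:10), n, TRUE), collapse = " ")
  for (i in 1:20) {
    base <- pad(15)
    with_bigram <- paste(base, "alpha beta")
    without <- paste(base, pad(2))
    idx <- build_index(list(dataset_doc("da", with_bigram, ""),
                            dataset_doc("db", without, "")))
    q <- tagged_query(c("alpha", "beta"), "q")
    expect_gte(score_mrf(q, "da", idx), score_mrf(q, "db", idx))
  }
})

test_that("tfidf scoring is a cosine: self-similarity 1, disjoint 0, oracle match", {
  toks <- list(d1 = c("gene", "disease"), d2 = c("other", "terms"),
               d3 = c("gene", "gene", "other"))
  docs <- lapply(names(toks), function(d)
    dataset_doc(d, paste(toks[[d]], collapse = " "), ""))
  idx <- build_index(docs)
  cfg <- clique_config(field_weights = c(1, 0))
  q <- tagged_query(c("gene", "disease"), "q")
  expect_equal(score_tfidf(q, "d1", idx, cfg), 1.0, tolerance = 1e-9)
  expect_equal(score_tfidf(q, "d2", idx, cfg), 0.0)
  set.seed(31)
  for (i in 1:20) {
    toks <- lapply(1:5, function(j) sample(sprintf("w%d", 1:15),
                                           sample(3:12, 1), replace = TRUE))
    names(toks) <- sprintf("d%d", 1:5)
    docs <- lapply(names(toks), function(d)
      dataset_doc(d, paste(toks[[d]], collapse = " "), ""))
    idx <- build_index(docs)
    qt <- sample(sprintf("w%d", 1:15), 3)
    q <- tagged_query(qt, "q")
    d <- sample(names(toks), 1)
    expect_equal(score_tfidf(q, d, idx, cfg),
                 oracle_tfidf_cosine(qt, toks, d), tolerance = 1e-9)
  }
})

test_that("retrieve ranks the unique all-terms doc first under every model", {
  set.seed(41)
  docs <- random_docs(50, vocab = sprintf("v%02d", 1:20))
  docs[[51]] <- dataset_doc("planted", "qq1 qq2 qq3 qq1 qq2 qq3", "qq1 qq2 qq3")
  idx <- build_index(docs)
  q <- tagged_query(c("qq1", "qq2", "qq3"), "q")
  for (model in c("tfidf", "ql", "mrf", "posmrf")) {
    rl <- retrieve(idx, q, model, k = 10)
    expect_identical(rl$doc_id[1], "planted")
  }
})

test_that("retrieve returns all matches when K exceeds them, deterministically", {
  idx <- build_index(tiny_docs())
  q <- tagged_query(c("gene", "disease"), "q")
  r1 <- retrieve(idx, q, "posmrf", k = 1000)
  expect_identical(sort(r1$doc_id), c("d1", "d2"))  # d3 has no term match
  expect_identical(retrieve(idx, q, "posmrf", k = 1000), r1)
  expect_error(retrieve(idx, q, "posmrf", k = 0), "k must be")
  expect_error(retrieve(idx, q, "nosuch"), "arg")
  expect_warning(r0 <- retrieve(idx, tagged_query("", "qe"), "mrf"), "empty query")
  expect_identical(nrow(r0), 0L)
})
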