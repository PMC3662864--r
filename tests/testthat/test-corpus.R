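test_that("matching is boundary-anchored, case-sensitive and leftmost-longest", {
  lex <- test_lexicon()
  doc <- test_document(title = "Neuropathic pain in rats",
                       abstract = "chronic neuropathic pain remains; cfa was given",
                       mesh = NULL)
  m <- match_terms(doc, lex)
  # leftmost-longest: "neuropathic pain" wins over nested "pain"
  ab <- m[m$section == "abstract", ]
  expect_equal(ab$matched_synonym, "neuropathic pain")
  expect_equal(ab$start, 8L)
  expect_equal(ab$end, 24L)
  # spans reproduce the synonym exactly
  expect_equal(substring(doc$abstract, ab$start + 1L, ab$end),
               ab$matched_synonym)
  # case sensitivity: "cfa" does not match synonym "CFA"
  expect_false("T4" %in% m$term_id)
  # no partial-token hits
  doc2 <- test_document(doc_id = "D2", title = "pains and painful states",
                        abstract = "", mesh = NULL)
  expect_equal(nrow(match_terms(doc2, lex)), 0L)
})

test_that("document scores follow weight-times-position over all mentions", {
  lex <- test_lexicon()
  w <- default_section_weights()
  mk <- function(term, section, n = 1L) {
    tibble::tibble(term_id = rep(term, n), matched_synonym = "x",
                   section = section, paragraph_index = NA_integer_,
                   sentence_index = 0L, start = 0L, end = 1L)
  }
  # specific in title: 2 x 2
  expect_equal(score_document(mk("T1", "title"), lex)$overall, 4)
  # relevant in body: 1 x 0.25
  expect_equal(score_document(mk("T3", "body"), lex)$overall, 0.25)
  # specific abstract + relevant mesh + specific twice in body
  ms <- rbind(mk("T1", "abstract"), mk("T3", "mesh"), mk("T2", "body", 2L))
  sc <- score_document(ms, lex)
  expect_equal(sc$overall, 2 + 1 + 2 * (2 * 0.25))
  expect_equal(sum(sc$per_category), sc$overall)
  expect_equal(sum(sc$per_term), sc$overall)
  # empty match set scores zero
  expect_equal(score_document(mk("T1", "title")[0, ], lex)$overall, 0)
  expect_error(score_document(mk("T9", "title"), lex), "unknown term")
})

test_that("score is monotone in matches and dominated by position", {
  lex <- test_lexicon()
  base <- tibble::tibble(term_id = "T1", matched_synonym = "x",
                         section = "body", paragraph_index = 0L,
                         sentence_index = 0L, start = 0L, end = 1L)
  s0 <- score_document(base, lex)$overall
  for (extra_section in c("body", "mesh", "abstract", "title")) {
    extra <- base
    extra$section <- extra_section
    s1 <- score_document(rbind(base, extra), lex)$overall
    expect_gt(s1, s0)
  }
  contribution <- function(section) {
    m <- base
    m$section <- section
    score_document(m, lex)$overall
  }
  expect_lt(contribution("body"), contribution("abstract"))
  expect_lt(contribution("abstract"), contribution("title"))
})

test_that("retrieval keeps only documents with a specific-term match", {
  lex <- test_lexicon()
  d_specific <- test_document(doc_id = "A", title = "About pain", abstract = "",
                              mesh = NULL)
  d_relevant <- test_document(doc_id = "B", title = "The locus caeruleus",
                              abstract = "", mesh = NULL)
  d_none <- test_document(doc_id = "C", title = "Unrelated work", abstract = "",
                          mesh = NULL)
  corpus <- build_corpus(list(d_specific, d_relevant, d_none), lex)
  expect_equal(vapply(corpus$documents, function(d) d$doc_id, ""), "A")
  expect_gte(corpus$scores$overall, 0.25)
  # scores use relevant matches too once retained
  d_both <- test_document(doc_id = "E", title = "pain and the locus caeruleus",
                          abstract = "", mesh = NULL)
  both <- build_corpus(list(d_both), lex)
  expect_equal(both$scores$overall, 2 * 2 + 1 * 2)
  expect_error(build_corpus(list(d_specific, d_specific), lex),
               "duplicate doc_id")
  empty <- build_corpus(list(), lex)
  expect_equal(length(empty$documents), 0L)
  expect_equal(nrow(empty$scores), 0L)
})

test_that("abbreviation capture registers document-local synonyms", {
  lex <- test_lexicon()
  doc <- test_document(
    abstract = "Rats received morphine (MOR) injections. MOR reduced responses.",
    mesh = NULL, title = "pain model")
  with_abbrev <- match_terms(doc, lex, abbreviations = TRUE)
  without <- match_terms(doc, lex, abbreviations = FALSE)
  expect_equal(sum(without$matched_synonym == "MOR"), 0L)
  expect_equal(sum(with_abbrev$matched_synonym == "MOR"), 2L)
  expect_true(all(with_abbrev$term_id[with_abbrev$matched_synonym == "MOR"] == "T4"))
})

test_that("stratified sampling is banded, capped and reproducible", {
  scores <- tibble::tibble(
    doc_id = sprintf("D%04d", 1:1000),
    overall = withr::with_seed(1, round(stats::rexp(1000, 1 / 15), 2))
  )
  bands <- list(c(1, 3), c(3, 10), c(10, 25), c(25, 50), c(50, Inf))
  sel <- stratified_sample(scores, bands, k = 10, seed = 9)
  expect_equal(length(sel), 5L)
  all_ids <- unlist(sel)
  expect_equal(anyDuplicated(all_ids), 0L)
  for (i in seq_along(bands)) {
    got <- scores[scores$doc_id %in% sel[[i]], ]
    expect_true(all(got$overall >= bands[[i]][1] & got$overall < bands[[i]][2]))
    expect_lte(length(sel[[i]]), 10L)
  }
  # same seed reproduces; band with fewer members than k returns all
  expect_identical(stratified_sample(scores, bands, 10, seed = 9), sel)
  tiny <- scores[1:2, ]
  tiny$overall <- c(1.5, 2.5)
  out <- stratified_sample(tiny, list(c(1, 3)), 10, seed = 1)
  expect_setequal(out[["[1,3)"]], tiny$doc_id)
  expect_error(stratified_sample(scores, bands, 0, seed = 1), "positive")
  expect_error(stratified_sample(scores, list(c(1, 5), c(4, 8)), 3, seed = 1),
               "overlap")
})

test_that("rank-sum comparison matches exact enumeration and detects shifts", {
  # identical samples: no separation
  same <- compare_mesh_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_lt(abs(same$statistic), 1e-9)
  # complete separation at n = 3 vs 3: exact two-sided p = 2/20
  sep <- compare_mesh_groups(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$p_value, rank_sum_exact_p(c(10, 11, 12), c(1, 2, 3)))
  expect_equal(sep$p_value, 0.1)
  # exact enumeration oracle across random small untied samples
  withr::with_seed(4, {
    for (rep in 1:20) {
      n1 <- sample(2:6, 1)
      n2 <- sample(2:6, 1)
      x <- sample(seq_len(50), n1)
      y <- sample(seq(10, 120), n2) + 0.5
      got <- compare_mesh_groups(x, y)
      expect_equal(got$p_value, rank_sum_exact_p(x, y), tolerance = 1e-9)
    }
  })
  # a shifted distribution at n = 500 is detected decisively
  withr::with_seed(11, {
    major <- stats::rnorm(500, mean = 2)
    minor <- stats::rnorm(500)
  })
  shift <- compare_mesh_groups(major, minor)
  expect_lt(shift$p_value, 0.001)
  expect_gt(shift$statistic, 0)
  expect_error(compare_mesh_groups(numeric(), 1:3), "non-empty")
})
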