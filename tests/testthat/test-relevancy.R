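mk_match <- function(term_id = "T2", section = "body", paragraph_index = NA_integer_,
                     sentence_index = 0L, start = 0L, end = 4L) {
  tibble::tibble(term_id = term_id, matched_synonym = "pain", section = section,
                 paragraph_index = paragraph_index,
                 sentence_index = sentence_index, start = start, end = end)
}

mk_body_mention <- function(doc, paragraph_index, sentence_index = 0L,
                            sentence_text = "GENE1 binds GENE2 tightly.") {
  root <- event_node("binding", list(mk_gene(1), mk_gene(2)),
                     trigger_text = "binds", trigger_start = 6L,
                     trigger_end = 11L)
  event_chain_mention(doc$doc_id, sentence_text, root, section = "body",
                      paragraph_index = paragraph_index,
                      sentence_index = sentence_index, confidence = 0.5)
}

test_that("tier scores follow section evidence and clamp to [5, 100]", {
  doc <- test_document(body = c(
    "The pain response was severe. GENE1 binds GENE2 tightly.",
    "Another paragraph.", "Another paragraph.", "Another paragraph.",
    "Another paragraph.", "Another paragraph.", "A distant pain paragraph."
  ))
  mention <- mk_body_mention(doc, paragraph_index = 0L, sentence_index = 1L)

  # same paragraph, different sentence
  same_par <- term_event_relevancy(
    mk_match(section = "body", paragraph_index = 0L, sentence_index = 0L,
             start = 4L, end = 8L), mention, doc)
  expect_equal(same_par$score, 60)
  expect_equal(same_par$evidence, "same_paragraph")
  # title / mesh / abstract tiers
  expect_equal(term_event_relevancy(
    mk_match(section = "title", start = 12L, end = 16L), mention, doc)$score, 55)
  expect_equal(term_event_relevancy(
    mk_match(section = "mesh", start = 0L, end = 4L), mention, doc)$score, 50)
  expect_equal(term_event_relevancy(
    mk_match(section = "abstract", start = 11L, end = 15L), mention, doc)$score, 45)
  # adjacent body paragraph
  adj <- term_event_relevancy(
    mk_match(section = "body", paragraph_index = 1L, start = 8L, end = 17L),
    mention, doc)
  expect_equal(adj$score, 30)
  expect_equal(adj$evidence, "same_section")
  # six paragraphs away hits the floor: max(5, 25 - 5*5) = 5
  far <- term_event_relevancy(
    mk_match(section = "body", paragraph_index = 6L, start = 10L, end = 14L),
    mention, doc)
  expect_equal(far$score, 5)
  expect_equal(far$evidence, "distant")
  # mismatched documents refuse to score
  other <- test_document(doc_id = "OTHER")
  expect_error(term_event_relevancy(mk_match(), mention, other), "belongs")
})

test_that("same-sentence scores sit in [75, 100] and grow with proximity", {
  body <- "Severe pain limits GENE1 binding responses in this model system today."
  doc <- test_document(body = body)
  mention <- mk_body_mention(doc, paragraph_index = 0L, sentence_index = 0L,
                             sentence_text = body)
  mention$root$trigger_start <- 25L # "binding"
  near <- term_event_relevancy(
    mk_match(section = "body", paragraph_index = 0L, sentence_index = 0L,
             start = 7L, end = 11L), mention, doc)
  expect_equal(near$evidence, "same_sentence")
  expect_gte(near$score, 75)
  expect_lte(near$score, 100)
  # spec'd arithmetic: d tokens apart in an L-token sentence
  toks <- nchar(strsplit(body, " ")[[1]])
  L <- length(strsplit(body, " ")[[1]])
  d <- 3L # pain (token 2) vs binding (token 5)
  expect_equal(near$score, 75 + round(25 * (1 - d / (L - 1))))
  # a term farther from the trigger scores lower but never below 75
  far_term_start <- as.integer(regexpr("today", body)) - 1L
  far <- term_event_relevancy(
    mk_match(section = "body", paragraph_index = 0L, sentence_index = 0L,
             start = far_term_start, end = far_term_start + 5L), mention, doc)
  expect_lt(far$score, near$score)
  expect_gte(far$score, 75)
})

test_that("relevancy links always land in [5, 100] across random placements", {
  doc <- test_document(body = replicate(8, "Filler paragraph text here."))
  withr::with_seed(31, {
    for (i in 1:50) {
      sec <- sample(c("title", "abstract", "mesh", "body"), 1)
      par <- if (sec == "body") sample(0:7, 1) else NA_integer_
      mention <- mk_body_mention(doc, paragraph_index = sample(0:7, 1))
      lk <- term_event_relevancy(
        mk_match(section = sec, paragraph_index = par,
                 sentence_index = 0L, start = 0L, end = 4L), mention, doc)
      expect_gte(lk$score, 5)
      expect_lte(lk$score, 100)
    }
  })
})

test_that("overall relevancy thresholds, weights and averages per document", {
  lex <- test_lexicon()
  g <- group_event_chains(list(mk_binding_mention(1, 2, "D1")))
  link <- function(term, doc, s) {
    tibble::tibble(term_id = term, doc_id = doc, score = s)
  }
  # nothing above 50 scores zero
  low <- overall_relevancy(g[1, ], link("T1", "D1", 45), lex)
  expect_equal(low$score, 0)
  expect_equal(low$band, "low")
  # one specific term at 100 in the only document: 2 * (50/50) = 2
  high <- overall_relevancy(g[1, ], link("T1", "D1", 100), lex)
  expect_equal(high$score, 2)
  expect_equal(high$band, "high")
  # two documents, one specific term at 75 in one of them: 2*0.5 / 2 = 0.5
  g2 <- group_event_chains(list(mk_binding_mention(1, 2, "D1"),
                                mk_binding_mention(1, 2, "D2")))
  med <- overall_relevancy(g2[1, ], link("T1", "D1", 75), lex)
  expect_equal(med$score, 0.5)
  expect_equal(med$band, "medium")
  # unweighted (disease) variant halves the specific-term contribution
  dis <- overall_relevancy(g[1, ], link("T1", "D1", 100), NULL)
  expect_equal(dis$score, 1)
  # per-document max, not sum, over a term's repeated links
  rep2 <- overall_relevancy(
    g[1, ], rbind(link("T1", "D1", 80), link("T1", "D1", 90)), lex)
  expect_equal(rep2$score, 2 * (90 - 50) / 50)
})

test_that("overall relevancy is monotone in link scores and diluted by documents", {
  lex <- test_lexicon()
  g2 <- group_event_chains(list(mk_binding_mention(1, 2, "D1"),
                                mk_binding_mention(1, 2, "D2")))
  links <- tibble::tibble(term_id = c("T1", "T3"), doc_id = c("D1", "D2"),
                          score = c(70, 60))
  base <- overall_relevancy(g2[1, ], links, lex)$score
  links_up <- links
  links_up$score[1] <- 95
  expect_gt(overall_relevancy(g2[1, ], links_up, lex)$score, base)
  # adding a document with no qualifying terms dilutes the average
  g3 <- group_event_chains(list(mk_binding_mention(1, 2, "D1"),
                                mk_binding_mention(1, 2, "D2"),
                                mk_binding_mention(1, 2, "D3")))
  expect_lt(overall_relevancy(g3[1, ], links, lex)$score, base)
  # doubling a term's weight doubles its contribution
  weighted <- overall_relevancy(g2[1, ], links[1, ], lex)$score
  unweighted <- overall_relevancy(g2[1, ], links[1, ], NULL)$score
  expect_equal(weighted, 2 * unweighted)
})

test_that("disease matching reuses the dictionary matcher independently", {
  disease_lex <- load_lexicon(write_lexicon_tsv(
    "DIS1\tdiabetes mellitus\tdisorder\trelevant\tdiabetes mellitus"
  ))
  doc <- test_document(abstract = "Links between diabetes mellitus and pain.",
                       mesh = NULL)
  dm <- match_disease_terms(doc, disease_lex)
  expect_equal(dm$term_id, "DIS1")
  expect_equal(dm$section, "abstract")
  pain <- match_terms(doc, test_lexicon())
  expect_false(any(pain$term_id %in% dm$term_id))
  empty_lex <- load_lexicon(write_lexicon_tsv(character()))
  expect_equal(nrow(match_disease_terms(doc, empty_lex)), 0L)
})
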