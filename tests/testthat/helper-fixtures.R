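# Shared fixture builders. Everything is constructed in code; no files are
# shipped with the tests.

write_lexicon_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- "term_id\tname\tcategory\tspecificity\tsynonyms"
  writeLines(c(header, rows), path)
  path
}

# A small pain-flavoured lexicon: two specific terms, two relevant.
test_lexicon <- function() {
  load_lexicon(write_lexicon_tsv(c(
    "T1\tneuropathic pain\tpain type\tspecific\tneuropathic pain|Neuropathic pain",
    "T2\tpain\tdisorder\tspecific\tpain|Pain",
    "T3\tlocus caeruleus\tanatomy\trelevant\tlocus caeruleus|LC",
    "T4\tmorphine\tdrug\trelevant\tmorphine|CFA"
  )))
}

test_document <- function(doc_id = "D1",
                          title = "Neuropathic pain in rats",
                          abstract = "We studied pain. The locus caeruleus was imaged.",
                          mesh = data.frame(descriptor = "Pain", is_major = TRUE),
                          body = character(), source = "medline") {
  document(doc_id, title = title, abstract = abstract, mesh = mesh,
           body = body, source = source)
}

mk_gene <- function(id, symbol = sprintf("GENE%d", id)) {
  participant(symbol, start = 0L, end = nchar(symbol), entrez_id = id)
}

mk_binding_mention <- function(id_a, id_b, doc_id = "D1", confidence = 0.5,
                               negated = FALSE, speculated = FALSE,
                               anatomy = character()) {
  pa <- mk_gene(id_a)
  pb <- mk_gene(id_b)
  root <- event_node("binding", list(pa, pb), trigger_text = "binds",
                     trigger_start = 5L, trigger_end = 10L)
  event_chain_mention(doc_id, sprintf("GENE%d binds GENE%d.", id_a, id_b),
                      root, confidence = confidence, negated = negated,
                      speculated = speculated, anatomy_terms = anatomy)
}

mk_regulation_mention <- function(cause_id, theme_id, doc_id = "D1",
                                  type = "positive_regulation",
                                  nested = FALSE, confidence = 0.5,
                                  negated = FALSE, speculated = FALSE) {
  cause <- mk_gene(cause_id)
  theme <- if (nested) {
    event_node("gene_expression", list(mk_gene(theme_id)),
               trigger_text = "expression", trigger_start = 20L,
               trigger_end = 30L)
  } else {
    mk_gene(theme_id)
  }
  root <- event_node(type, list(theme), cause = cause,
                     trigger_text = "augments", trigger_start = 9L,
                     trigger_end = 17L)
  event_chain_mention(doc_id,
                      sprintf("GENE%d augments GENE%d.", cause_id, theme_id),
                      root, confidence = confidence, negated = negated,
                      speculated = speculated)
}

# Random mentions over a limited template space so that groups repeat.
random_chain_mentions <- function(n, seed, n_genes = 12L, n_docs = 8L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ids <- sample.int(n_genes, 2L) + 100L
      doc <- sprintf("D%d", sample.int(n_docs, 1L))
      kind <- sample(c("binding", "binding_swapped", "regulation", "nested"), 1L)
      switch(kind,
        binding = mk_binding_mention(ids[1], ids[2], doc,
                                     confidence = runif(1),
                                     negated = runif(1) < 0.2,
                                     speculated = runif(1) < 0.1),
        binding_swapped = mk_binding_mention(ids[2], ids[1], doc,
                                             confidence = runif(1)),
        regulation = mk_regulation_mention(ids[1], ids[2], doc,
                                           type = sample(c("regulation",
                                             "positive_regulation",
                                             "negative_regulation"), 1L),
                                           confidence = runif(1)),
        nested = mk_regulation_mention(ids[1], ids[2], doc, nested = TRUE,
                                       confidence = runif(1))
      )
    })
  })
}

# Exact two-sided rank-sum p-value by enumeration of all rank assignments.
rank_sum_exact_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Two-sided Fisher p by full hypergeometric enumeration over tables with
# the observed margins.
fisher_exact_enum_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(m, k)
  support <- lo:hi
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

default_bundle <- function(seed = 101, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_bundle(sim_config(seed = seed), dir)
  dir
}
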