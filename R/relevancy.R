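#' Default tier table for term-to-event relevancy
#'
#' The scoring constants behind [term_event_relevancy()]. Same-sentence
#' co-occurrence scores in the 75-100 band, scaled by token proximity;
#' progressively weaker evidence tiers (same paragraph, title, MeSH,
#' abstract, adjacent body paragraph) take fixed values; distant body
#' placements decay with the paragraph gap down to the floor of 5.
#' All values are editable, e.g. to recalibrate tiers against observed
#' curation precision.
#'
#' @return A named list of numeric constants.
#' @export
default_relevancy_tiers <- function() {
  list(
    same_sentence_base = 75, same_sentence_range = 25,
    same_paragraph = 60, title = 55, mesh = 50, abstract = 45,
    adjacent_paragraph = 30, distant_base = 25, distant_step = 5, floor = 5
  )
}

#' Score the relevance of one term mention to one event-chain mention
#'
#' Produces a 5-100 relevancy score for a (term match, event mention) pair
#' in the same document, reflecting the likelihood that the term pertains to
#' the event. Evidence tiers, strongest first:
#'
#' * same sentence: `75 + round(25 * (1 - d / max(L - 1, 1)))` where `d` is
#'   the token distance between the term and the event trigger and `L` the
#'   sentence token count -- adjacency approaches 100, opposite ends of a
#'   long sentence approach 75;
#' * same paragraph (different sentence): 60;
#' * term in the title: 55; term in a MeSH descriptor: 50; term in the
#'   abstract with the event elsewhere: 45;
#' * adjacent body paragraph: 30; farther body placements decay as
#'   `max(5, 25 - 5 * (gap - 1))` with the paragraph gap.
#'
#' Scores are clamped to `[5, 100]`; same-sentence links are always >= 75.
#'
#' @param term_match One row of a [match_terms()] tibble.
#' @param mention A `tm_mention` from the same document.
#' @param doc The `tm_document` both refer to.
#' @param tiers Tier constants; see [default_relevancy_tiers()].
#' @return A one-row tibble: `term_id`, `score`, `evidence`.
#' @export
term_event_relevancy <- function(term_match, mention, doc,
                                 tiers = default_relevancy_tiers()) {
  stopifnot(inherits(mention, "tm_mention"), inherits(doc, "tm_document"))
  if (!is.null(mention$doc_id) && mention$doc_id != doc$doc_id) {
    stopf("mention belongs to document %s, not %s", mention$doc_id, doc$doc_id)
  }
  term_match <- as.list(term_match[1, ])
  same_unit <-
    term_match$section == mention$section &&
    (term_match$section != "body" ||
       identical(term_match$paragraph_index, mention$paragraph_index))
  score <- NA_real_
  evidence <- NA_character_
  if (same_unit && identical(as.integer(term_match$sentence_index),
                             mention$sentence_index)) {
    toks <- tokenize_spans(mention$sentence_text)
    L <- max(nrow(toks), 1L)
    unit_text <- switch(term_match$section,
      title = doc$title, abstract = doc$abstract,
      body = doc$body[term_match$paragraph_index + 1L], "")
    sents <- split_sentences(unit_text)
    sent_off <- if (nrow(sents) > mention$sentence_index) {
      sents$start[mention$sentence_index + 1L]
    } else 0L
    term_pos <- term_match$start - sent_off
    trig_pos <- mention$root$trigger_start
    d <- abs(
      (token_index_at(toks, term_pos) %||% 1L) -
      (token_index_at(toks, trig_pos) %||% 1L)
    )
    if (is.na(d)) d <- 0L
    score <- tiers$same_sentence_base +
      round(tiers$same_sentence_range * (1 - d / max(L - 1L, 1L)))
    evidence <- "same_sentence"
  } else if (same_unit) {
    score <- tiers$same_paragraph
    evidence <- "same_paragraph"
  } else if (term_match$section == "title") {
    score <- tiers$title
    evidence <- "title"
  } else if (term_match$section == "mesh") {
    score <- tiers$mesh
    evidence <- "mesh"
  } else if (term_match$section == "abstract") {
    score <- tiers$abstract
    evidence <- "abstract"
  } else {
    # term in body, event in a different paragraph or section
    gap <- if (mention$section == "body" && !is.na(mention$paragraph_index)) {
      abs(term_match$paragraph_index - mention$paragraph_index)
    } else {
      term_match$paragraph_index + 1L
    }
    if (gap <= 1L) {
      score <- tiers$adjacent_paragraph
      evidence <- "same_section"
    } else {
      score <- max(tiers$floor,
                   tiers$distant_base - tiers$distant_step * (gap - 1L))
      evidence <- "distant"
    }
  }
  score <- min(100, max(5, score))
  tibble(term_id = term_match$term_id, score = as.numeric(score),
         evidence = evidence)
}

#' Overall relevancy of a grouped event chain to a topic
#'
#' Aggregates the individual term-to-mention relevancy links of a group into
#' a single score. Only links scoring above 50 count. Within each document
#' mentioning the group, each term contributes its specificity weight times
#' `(s - 50) / 50`, where `s` is the term's best link score in that document
#' (per-document max, so mention frequency is not double-counted); the sum is
#' averaged over the documents mentioning the group. For disease-term
#' relevancy pass `weights = NULL`: every term then weighs 1.
#'
#' Scores land on a 0-2-ish scale partitioned into bands: `low` (exactly 0),
#' `medium` (above 0, at most 1), `high` (above 1).
#'
#' @param group One row of a [group_event_chains()] tibble (or a list with a
#'   `mentions` element).
#' @param links Tibble with columns `term_id`, `doc_id`, `score`, restricted
#'   to this group's mentions.
#' @param lexicon A `topic_lexicon` supplying specificity weights, or `NULL`
#'   for unweighted (disease-style) aggregation.
#' @return A list: `score`, `band`, `per_term` (named contributions summed
#'   over documents, pre-averaging).
#' @export
overall_relevancy <- function(group, links, lexicon = NULL) {
  mentions <- if (is.data.frame(group)) group$mentions[[1]] else group$mentions
  docs <- unique(vapply(mentions, function(m) m$doc_id, ""))
  n_docs <- max(length(docs), 1L)
  if (nrow(links) == 0L) {
    return(list(score = 0, band = "low", per_term = numeric()))
  }
  links <- links[links$doc_id %in% docs, , drop = FALSE]
  best <- links |>
    dplyr::group_by(.data$doc_id, .data$term_id) |>
    dplyr::summarise(s = max(.data$score), .groups = "drop") |>
    dplyr::filter(.data$s > 50)
  if (nrow(best) == 0L) {
    return(list(score = 0, band = "low", per_term = numeric()))
  }
  w <- if (is.null(lexicon)) {
    rep(1, nrow(best))
  } else {
    idx <- match(best$term_id, lexicon$entries$term_id)
    if (anyNA(idx)) stopf("link refers to term absent from the lexicon")
    lexicon$entries$weight[idx]
  }
  contrib <- w * (best$s - 50) / 50
  score <- sum(contrib) / n_docs
  band <- if (score == 0) "low" else if (score <= 1) "medium" else "high"
  per_term <- tapply(contrib, best$term_id, sum)
  list(score = score, band = band,
       per_term = setNames(as.numeric(per_term), names(per_term)))
}

#' Match disease terms in a document
#'
#' Identical matching machinery to [match_terms()], applied with a disease
#' lexicon. Disease lexicons conventionally carry every term as
#' specificity `relevant` (weight 1), since disease relevancy aggregation is
#' unweighted.
#'
#' @inheritParams match_terms
#' @param disease_lexicon A `topic_lexicon` of disease terms.
#' @return A match tibble; see [match_terms()].
#' @export
match_disease_terms <- function(doc, disease_lexicon, abbreviations = FALSE) {
  match_terms(doc, disease_lexicon, abbreviations = abbreviations)
}
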