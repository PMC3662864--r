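#' Default English stop-word list
#'
#' A standard list of English function words used by [rank_candidates()] to
#' compute the stop-word fraction of candidate phrases. Configurable: pass
#' any character vector in its place.
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  c(
    "a", "about", "above", "after", "again", "against", "all", "also", "am",
    "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "had", "has", "have", "having", "he", "her",
    "here", "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it",
    "its", "itself", "just", "may", "me", "might", "more", "most", "must",
    "my", "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
    "other", "our", "ours", "out", "over", "own", "same", "she", "should",
    "so", "some", "such", "than", "that", "the", "their", "theirs", "them",
    "then", "there", "these", "they", "this", "those", "through", "to",
    "too", "under", "until", "up", "upon", "very", "was", "we", "were",
    "what", "when", "where", "which", "while", "who", "whom", "why", "will",
    "with", "would", "you", "your", "yours"
  )
}

#' Enumerate candidate multi-word phrases from corpus text
#'
#' Lowercases each text, splits it into sentences, and collects every
#' contiguous token n-gram of length `min_len` to `max_len` that does not
#' cross a sentence boundary, with its frequency across all input texts.
#' This is the raw material for the dictionary-building support tool: a
#' manual-review aid proposing phrases a curator might add as topic terms.
#'
#' @param texts Character vector of input texts.
#' @param min_len,max_len n-gram length bounds (`1 <= min_len <= max_len`).
#' @return Tibble with `phrase`, `frequency`, `length` (token count).
#' @export
extract_candidates <- function(texts, min_len = 2L, max_len = 4L) {
  if (!(min_len >= 1L && min_len <= max_len)) {
    stopf("need 1 <= min_len <= max_len")
  }
  grams <- character()
  for (text in texts) {
    for (sent in split_sentences(text)$sentence) {
      toks <- tokenize_spans(tolower(sent))$token
      n <- length(toks)
      for (len in seq.int(min_len, max_len)) {
        if (n < len) next
        starts <- seq_len(n - len + 1L)
        grams <- c(grams, vapply(starts, function(s) {
          paste(toks[s:(s + len - 1L)], collapse = " ")
        }, ""))
      }
    }
  }
  if (length(grams) == 0L) {
    return(tibble(phrase = character(), frequency = integer(),
                  length = integer()))
  }
  tab <- table(grams)
  tibble(
    phrase = names(tab),
    frequency = as.integer(tab),
    length = lengths(strsplit(names(tab), " ", fixed = TRUE))
  )
}

#' Rank candidate phrases by stop-word content
#'
#' Orders candidates for manual review: fewer stop words first, then higher
#' frequency, then longer phrases, then alphabetically. Phrases made up
#' entirely of stop words are dropped. The multi-key lexicographic order is
#' the simplest scheme honouring the ranking criteria (stop-word proportion
#' and size); no blended numeric score is computed.
#'
#' @param cands Tibble from [extract_candidates()].
#' @param stopwords Character vector; defaults to [default_stopwords()].
#' @return The filtered candidates, with a `stop_fraction` column, in rank
#'   order.
#' @export
rank_candidates <- function(cands, stopwords = default_stopwords()) {
  if (nrow(cands) == 0L) {
    return(dplyr::mutate(cands, stop_fraction = numeric()))
  }
  toks <- strsplit(cands$phrase, " ", fixed = TRUE)
  cands$stop_fraction <- vapply(toks, function(t) mean(t %in% stopwords), 0)
  cands <- cands[cands$stop_fraction < 1, , drop = FALSE]
  cands[order(cands$stop_fraction, -cands$frequency, -cands$length,
              cands$phrase, method = "radix"), , drop = FALSE]
}
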