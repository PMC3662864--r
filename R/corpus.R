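#' Construct a sectioned literature document
#'
#' A document carries the sections the matcher and scorer understand: title,
#' abstract, MeSH descriptors (with major-topic flags), and optional full-text
#' body paragraphs. Abstract-only records are the norm for Medline-style
#' sources; full text is typical of open-access PMC-style sources.
#'
#' @param doc_id Unique document identifier.
#' @param title,abstract Section strings (may be empty).
#' @param mesh A data frame / tibble with columns `descriptor` (character) and
#'   `is_major` (logical), or `NULL`.
#' @param body Character vector of body paragraphs (may be empty).
#' @param source `"medline"` or `"pmc"`.
#' @return A list of class `tm_document`.
#' @export
document <- function(doc_id, title = "", abstract = "", mesh = NULL,
                     body = character(), source = c("medline", "pmc")) {
  source <- match.arg(source)
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    stopf("doc_id must be a non-empty string")
  }
  if (is.null(mesh)) {
    mesh <- tibble(descriptor = character(), is_major = logical())
  } else {
    mesh <- as_tibble(mesh)
    stopifnot(all(c("descriptor", "is_major") %in% names(mesh)))
  }
  structure(
    list(doc_id = doc_id, title = title, abstract = abstract,
         mesh = mesh, body = as.character(body), source = source),
    class = "tm_document"
  )
}

#' Read documents from JSON Lines
#'
#' One document per line with fields `doc_id`, `title`, `abstract`, `mesh`
#' (array of `{descriptor, is_major}`), `body` (array of paragraph strings)
#' and `source`.
#'
#' @param path Path to a `.jsonl` file.
#' @return A list of `tm_document` objects.
#' @export
read_documents <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    mesh <- if (length(x$mesh) > 0L) {
      tibble(
        descriptor = vapply(x$mesh, function(m) m$descriptor, ""),
        is_major = vapply(x$mesh, function(m) isTRUE(m$is_major), TRUE)
      )
    } else NULL
    document(
      doc_id = x$doc_id,
      title = x$title %||% "",
      abstract = x$abstract %||% "",
      mesh = mesh,
      body = unlist(x$body) %||% character(),
      source = x$source %||% "medline"
    )
  })
}

#' Write documents to JSON Lines
#'
#' @param docs List of `tm_document` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (doc in docs) {
    mesh <- lapply(seq_len(nrow(doc$mesh)), function(i) {
      list(descriptor = doc$mesh$descriptor[i], is_major = doc$mesh$is_major[i])
    })
    writeLines(jsonlite::toJSON(
      list(doc_id = doc$doc_id, title = doc$title, abstract = doc$abstract,
           mesh = mesh, body = as.list(doc$body), source = doc$source),
      auto_unbox = TRUE
    ), con)
  }
  invisible(path)
}

empty_matches <- function() {
  tibble(
    term_id = character(), matched_synonym = character(), section = character(),
    paragraph_index = integer(), sentence_index = integer(),
    start = integer(), end = integer()
  )
}

# Case-sensitive dictionary matches of `synonyms` in one text unit, with
# token-boundary anchoring and leftmost-longest overlap resolution.
match_unit <- function(text, synonyms, term_ids) {
  if (is.na(text) || !nzchar(text)) return(NULL)
  cand <- list()
  for (i in seq_along(synonyms)) {
    syn <- synonyms[i]
    m <- gregexpr(syn, text, fixed = TRUE)[[1]]
    if (m[1] == -1) next
    start <- as.integer(m)
    end <- start + nchar(syn) - 1L
    # boundary: flanked by non-alphanumeric characters or string edges
    before <- ifelse(start == 1L, "", substring(text, start - 1L, start - 1L))
    after <- ifelse(end == nchar(text), "", substring(text, end + 1L, end + 1L))
    ok <- !grepl("[[:alnum:]]", before) & !grepl("[[:alnum:]]", after)
    if (!any(ok)) next
    cand[[length(cand) + 1L]] <- tibble(
      term_id = term_ids[i], matched_synonym = syn,
      start = start[ok], end = end[ok]
    )
  }
  if (length(cand) == 0L) return(NULL)
  cand <- dplyr::bind_rows(cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  keep <- logical(nrow(cand))
  frontier <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > frontier) {
      keep[i] <- TRUE
      frontier <- cand$end[i]
    }
  }
  cand[keep, , drop = FALSE]
}

# Sentence index (0-based) of each 1-based start offset within `text`.
sentence_index_of <- function(text, starts) {
  sents <- split_sentences(text)
  if (nrow(sents) == 0L) return(rep(0L, length(starts)))
  vapply(starts, function(s) {
    idx <- which(sents$start < s & s <= sents$end)
    if (length(idx) == 0L) idx <- which.min(abs(sents$start + 1L - s))
    as.integer(idx[1] - 1L)
  }, integer(1))
}

#' Match lexicon terms in a document
#'
#' Deterministic case-sensitive dictionary matching over every section of a
#' document. Matches must be flanked by non-alphanumeric characters or string
#' edges (so `"pain"` never matches inside `"pains"`), and overlapping
#' candidates are resolved by the leftmost-longest rule, the standard
#' dictionary-NER convention.
#'
#' With `abbreviations = TRUE`, a parenthetical immediately following a
#' matched term -- as in `"complete Freund's adjuvant (CFA)"` -- registers the
#' abbreviation as a document-local synonym of the same term and the document
#' is rescanned once.
#'
#' @param doc A `tm_document`.
#' @param lexicon A `topic_lexicon`.
#' @param abbreviations Capture parenthetical abbreviations as document-local
#'   synonyms (default off).
#' @return A tibble of matches: `term_id`, `matched_synonym`, `section`
#'   (`title`/`abstract`/`mesh`/`body`), `paragraph_index` (0-based, body
#'   only), `sentence_index` (0-based within the text unit), and 0-based
#'   half-open `start`/`end` character offsets into the unit's text.
#' @export
match_terms <- function(doc, lexicon, abbreviations = FALSE) {
  stopifnot(inherits(doc, "tm_document"), inherits(lexicon, "topic_lexicon"))
  synonyms <- names(lexicon$index)
  term_ids <- unname(lexicon$index)
  scan <- function(synonyms, term_ids) {
    out <- list()
    add <- function(hits, section, paragraph_index, text) {
      if (is.null(hits) || nrow(hits) == 0L) return()
      hits$section <- section
      hits$paragraph_index <- paragraph_index
      hits$sentence_index <- if (section %in% c("title", "abstract", "body")) {
        sentence_index_of(text, hits$start)
      } else 0L
      out[[length(out) + 1L]] <<- hits
    }
    add(match_unit(doc$title, synonyms, term_ids), "title", NA_integer_, doc$title)
    add(match_unit(doc$abstract, synonyms, term_ids), "abstract", NA_integer_, doc$abstract)
    for (i in seq_len(nrow(doc$mesh))) {
      add(match_unit(doc$mesh$descriptor[i], synonyms, term_ids), "mesh",
          NA_integer_, doc$mesh$descriptor[i])
    }
    for (p in seq_along(doc$body)) {
      add(match_unit(doc$body[p], synonyms, term_ids), "body", p - 1L, doc$body[p])
    }
    if (length(out) == 0L) return(empty_matches())
    res <- dplyr::bind_rows(out)
    # convert to 0-based half-open spans
    res$start <- res$start - 1L
    res[, c("term_id", "matched_synonym", "section", "paragraph_index",
            "sentence_index", "start", "end")]
  }
  res <- scan(synonyms, term_ids)
  if (abbreviations && nrow(res) > 0L) {
    extra <- abbreviation_synonyms(doc, res)
    new <- !extra$abbrev %in% synonyms
    if (any(new)) {
      res <- scan(c(synonyms, extra$abbrev[new]), c(term_ids, extra$term_id[new]))
    }
  }
  res
}

# Parenthetical abbreviations directly after a match, e.g. "term (ABC)".
abbreviation_synonyms <- function(doc, matches) {
  section_text <- function(row) {
    switch(row$section,
      title = doc$title, abstract = doc$abstract,
      body = doc$body[row$paragraph_index + 1L], mesh = ""
    )
  }
  out <- tibble(term_id = character(), abbrev = character())
  for (i in seq_len(nrow(matches))) {
    row <- matches[i, ]
    text <- section_text(row)
    tail <- substring(text, row$end + 1L, min(nchar(text), row$end + 16L))
    m <- regmatches(tail, regexec("^ \\(([A-Za-z][A-Za-z0-9-]{1,9})\\)", tail))[[1]]
    if (length(m) == 2L) {
      out <- dplyr::bind_rows(out, tibble(term_id = row$term_id, abbrev = m[2]))
    }
  }
  dplyr::distinct(out)
}

#' Default document section weights
#'
#' Positional weights for document relevance scoring: a mention in the title
#' counts 2, in the abstract or a MeSH descriptor 1, and in the body 0.25.
#' Overridable, e.g. to damp the advantage full-text articles gain from their
#' sheer volume of body text.
#'
#' @return Named numeric vector with entries `title`, `abstract`, `mesh`, `body`.
#' @export
default_section_weights <- function() {
  c(title = 2, abstract = 1, mesh = 1, body = 0.25)
}

#' Score a document's topic relevance
#'
#' Every term mention contributes its specificity weight (specific 2,
#' relevant 1) times its section weight; the overall document score is the
#' sum over all mentions, with repeated mentions each counting. Per-category
#' and per-term breakdowns use the same mention scores.
#'
#' @param matches A match tibble from [match_terms()].
#' @param lexicon The `topic_lexicon` the matches refer to.
#' @param section_weights Named weights per section; see
#'   [default_section_weights()].
#' @return A list with `overall` (numeric), `per_category` and `per_term`
#'   (named numerics summing to `overall`).
#' @export
score_document <- function(matches, lexicon,
                           section_weights = default_section_weights()) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  if (nrow(matches) == 0L) {
    return(list(overall = 0, per_category = numeric(), per_term = numeric()))
  }
  idx <- match(matches$term_id, lexicon$entries$term_id)
  if (anyNA(idx)) {
    stopf("match refers to unknown term %s",
          sQuote(matches$term_id[which(is.na(idx))[1]]))
  }
  t_i <- lexicon$entries$weight[idx]
  p_i <- section_weights[matches$section]
  if (anyNA(p_i)) stopf("no section weight for %s", matches$section[is.na(p_i)][1])
  mention_scores <- t_i * unname(p_i)
  per_term <- tapply(mention_scores, matches$term_id, sum)
  per_category <- tapply(mention_scores, lexicon$entries$category[idx], sum)
  list(
    overall = sum(mention_scores),
    per_category = setNames(as.numeric(per_category), names(per_category)),
    per_term = setNames(as.numeric(per_term), names(per_term))
  )
}

#' Build a topic corpus from a document stream
#'
#' Retrieval uses only `specific` terms: a document enters the corpus iff it
#' has at least one match of a specificity-specific term. Scores for retained
#' documents are then computed from all matches, specific and relevant alike.
#'
#' @param docs List of `tm_document` objects.
#' @param lexicon A `topic_lexicon`.
#' @param section_weights Passed to [score_document()].
#' @param abbreviations Passed to [match_terms()].
#' @return A list with `documents` (retained docs), `matches` (tibble over
#'   retained docs with a `doc_id` column), and `scores` (tibble: `doc_id`,
#'   `overall`, one column per category).
#' @export
build_corpus <- function(docs, lexicon,
                         section_weights = default_section_weights(),
                         abbreviations = FALSE) {
  ids <- vapply(docs, function(d) d$doc_id, "")
  if (anyDuplicated(ids)) {
    stopf("duplicate doc_id %s", sQuote(ids[duplicated(ids)][1]))
  }
  specific_ids <- lexicon$entries$term_id[lexicon$entries$specificity == "specific"]
  kept <- list(); kept_matches <- list(); kept_scores <- list()
  for (doc in docs) {
    m <- match_terms(doc, lexicon, abbreviations = abbreviations)
    if (nrow(m) == 0L || !any(m$term_id %in% specific_ids)) next
    sc <- score_document(m, lexicon, section_weights)
    m$doc_id <- doc$doc_id
    kept[[length(kept) + 1L]] <- doc
    kept_matches[[length(kept_matches) + 1L]] <- m
    kept_scores[[length(kept_scores) + 1L]] <-
      c(list(doc_id = doc$doc_id, overall = sc$overall), as.list(sc$per_category))
  }
  matches <- if (length(kept_matches) > 0L) {
    dplyr::bind_rows(kept_matches) |>
      dplyr::relocate("doc_id")
  } else {
    dplyr::mutate(empty_matches(), doc_id = character(), .before = 1L)
  }
  scores <- if (length(kept_scores) > 0L) {
    dplyr::bind_rows(lapply(kept_scores, as_tibble))
  } else {
    tibble(doc_id = character(), overall = numeric())
  }
  scores[is.na(scores)] <- 0
  list(documents = kept, matches = matches, scores = scores)
}

#' Stratified sample of documents by score band
#'
#' Samples up to `k` document ids without replacement from each half-open
#' score band `[lo, hi)`; bands with fewer than `k` members return all
#' members. Reproducible for a given seed.
#'
#' @param scores A data frame with columns `doc_id` and `overall`.
#' @param bands List of two-element numeric vectors `c(lo, hi)`; must not
#'   overlap. `Inf` is a valid upper bound.
#' @param k Maximum sample size per band (positive integer).
#' @param seed Integer seed.
#' @return Named list mapping `"[lo,hi)"` to a character vector of doc ids.
#' @export
stratified_sample <- function(scores, bands, k, seed) {
  if (!is_count(k) || k <= 0) stopf("k must be a positive integer")
  bands <- lapply(bands, as.numeric)
  if (any(vapply(bands, function(b) length(b) != 2L || b[1] >= b[2], TRUE))) {
    stopf("each band must be c(lo, hi) with lo < hi")
  }
  ord <- order(vapply(bands, `[`, 0, 1))
  sorted <- bands[ord]
  for (i in seq_along(sorted)[-1]) {
    if (sorted[[i]][1] < sorted[[i - 1]][2]) stopf("bands must not overlap")
  }
  withr::with_seed(seed, {
    out <- lapply(bands, function(b) {
      members <- scores$doc_id[scores$overall >= b[1] & scores$overall < b[2]]
      if (length(members) <= k) members else sample(members, k)
    })
    names(out) <- vapply(bands, function(b) sprintf("[%g,%g)", b[1], b[2]), "")
    out
  })
}

#' Compare document scores between MeSH major and minor groups
#'
#' Rank-sum (Mann-Whitney/Wilcoxon) comparison of two score distributions,
#' e.g. documents carrying a topic descriptor as a major versus a minor MeSH
#' topic. The Z statistic always comes from the tie-corrected normal
#' approximation; the p-value is the exact rank-sum probability when both
#' groups are small (n <= 50) and untied, and the normal approximation
#' otherwise.
#'
#' @param scores_major,scores_minor Non-empty numeric vectors.
#' @return A list with `statistic` (Z), `p_value` (two-sided), and `method`.
#' @export
compare_mesh_groups <- function(scores_major, scores_minor) {
  if (length(scores_major) == 0L || length(scores_minor) == 0L) {
    stopf("both score vectors must be non-empty")
  }
  n1 <- length(scores_major); n2 <- length(scores_minor)
  r <- rank(c(scores_major, scores_minor))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0
  exact_ok <- n1 <= 50 && n2 <= 50 && !any(ties > 1)
  if (exact_ok) {
    p <- suppressWarnings(
      wilcox.test(scores_major, scores_minor, exact = TRUE)$p.value
    )
    method <- "exact rank-sum"
  } else {
    p <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1
    method <- "normal approximation with tie correction"
  }
  list(statistic = z, p_value = min(1, p), method = method)
}
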