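#' Default topic-term category vocabulary
#'
#' The twelve category labels used by the shipped dictionaries. Terms in a
#' lexicon must carry one of these labels (or a label from a user-supplied
#' replacement vocabulary): categories describe what kind of concept a term
#' denotes, e.g. a disorder, a drug class, or an anatomical region.
#'
#' @return A character vector of category labels.
#' @export
default_term_categories <- function() {
  c(
    "pain type", "disorder", "drug", "drug class", "treatment",
    "surgical procedure", "anatomy", "condition", "molecule", "family",
    "gene", "physiology"
  )
}

specificity_weight <- function(specificity) {
  ifelse(specificity == "specific", 2L, 1L)
}

new_lexicon <- function(entries, categories) {
  syn_pairs <- tibble(
    synonym = as.character(unlist(entries$synonyms, use.names = FALSE)),
    term_id = rep(entries$term_id, lengths(entries$synonyms))
  )
  dup <- syn_pairs$synonym[duplicated(syn_pairs$synonym)]
  if (length(dup) > 0L) {
    offenders <- unique(syn_pairs$term_id[syn_pairs$synonym %in% dup])
    stopf(
      "ambiguous synonym(s) %s shared by entries %s",
      paste(sQuote(unique(dup)), collapse = ", "),
      paste(offenders, collapse = ", ")
    )
  }
  index <- setNames(syn_pairs$term_id, syn_pairs$synonym)
  structure(
    list(entries = entries, index = index, categories = categories),
    class = "topic_lexicon"
  )
}

#' Load a weighted topic-term lexicon
#'
#' Reads a tab-separated dictionary of topic terms. Each entry has an
#' identifier, a preferred name, a category, a specificity class, and a
#' pipe-delimited list of case-sensitive synonyms (the preferred name is
#' added to the synonyms if absent). Specificity determines the term weight
#' used in document scoring: `specific` terms weigh 2, `relevant` terms 1.
#' A synonym string may belong to only one entry; ambiguous synonyms are a
#' load error, since ambiguity inflates false-positive retrieval.
#'
#' @param path Path to a TSV file with header columns `term_id`, `name`,
#'   `category`, `specificity`, `synonyms`.
#' @param categories Allowed category vocabulary; defaults to
#'   [default_term_categories()].
#' @return A `topic_lexicon`: a list with an `entries` tibble
#'   (`term_id`, `preferred_name`, `category`, `specificity`, `weight`,
#'   `synonyms` list-column) and a synonym-to-term index.
#' @seealso [lexicon_stats()], [save_lexicon()]
#' @export
load_lexicon <- function(path, categories = default_term_categories()) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    quote = "", check.names = TRUE)
  required <- c("term_id", "name", "category", "specificity", "synonyms")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stopf("lexicon file lacks column(s): %s", paste(missing, collapse = ", "))
  }
  bad_cat <- which(!raw$category %in% categories)
  if (length(bad_cat) > 0L) {
    stopf(
      "unknown category %s in lexicon row %d (term %s)",
      sQuote(raw$category[bad_cat[1]]), bad_cat[1], raw$term_id[bad_cat[1]]
    )
  }
  bad_spec <- which(!raw$specificity %in% c("specific", "relevant"))
  if (length(bad_spec) > 0L) {
    stopf(
      "specificity must be 'specific' or 'relevant' in row %d (term %s)",
      bad_spec[1], raw$term_id[bad_spec[1]]
    )
  }
  if (anyDuplicated(raw$term_id)) {
    stopf("duplicate term_id %s", sQuote(raw$term_id[duplicated(raw$term_id)][1]))
  }
  synonyms <- lapply(seq_len(nrow(raw)), function(i) {
    syns <- strsplit(raw$synonyms[i], "|", fixed = TRUE)[[1]]
    syns <- syns[nzchar(syns)]
    syns <- union(raw$name[i], syns)
    if (anyDuplicated(syns)) {
      stopf("duplicate synonym within entry %s", raw$term_id[i])
    }
    syns
  })
  entries <- tibble(
    term_id = raw$term_id,
    preferred_name = raw$name,
    category = raw$category,
    specificity = raw$specificity,
    weight = specificity_weight(raw$specificity),
    synonyms = synonyms
  )
  new_lexicon(entries, categories)
}

#' Write a lexicon back to its TSV format
#'
#' @param lexicon A `topic_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  out <- data.frame(
    term_id = lexicon$entries$term_id,
    name = lexicon$entries$preferred_name,
    category = lexicon$entries$category,
    specificity = lexicon$entries$specificity,
    synonyms = vapply(lexicon$entries$synonyms, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a lexicon by category and specificity
#'
#' Counts terms and synonyms per (category, specificity) cell. Cells sum to
#' the lexicon totals, so the summary doubles as a consistency check.
#'
#' @param lexicon A `topic_lexicon`.
#' @return A tibble with columns `category`, `specificity`, `n_terms`,
#'   `n_synonyms`, one row per populated cell.
#' @export
lexicon_stats <- function(lexicon) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  e <- lexicon$entries
  if (nrow(e) == 0L) {
    return(tibble(category = character(), specificity = character(),
                  n_terms = integer(), n_synonyms = integer()))
  }
  e |>
    dplyr::mutate(n_syn = lengths(.data$synonyms)) |>
    dplyr::group_by(.data$category, .data$specificity) |>
    dplyr::summarise(
      n_terms = dplyr::n(),
      n_synonyms = sum(.data$n_syn),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category, .data$specificity)
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat(sprintf(
    "<topic_lexicon> %d terms (%d specific, %d relevant), %d synonyms\n",
    nrow(x$entries),
    sum(x$entries$specificity == "specific"),
    sum(x$entries$specificity == "relevant"),
    length(x$index)
  ))
  invisible(x)
}

#' @importFrom rlang .data
NULL
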