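AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")
names(AA1) <- AA3

aa_from_token <- function(tok) {
  if (nchar(tok) == 1L) return(toupper(tok))
  unname(AA1[paste0(toupper(substring(tok, 1, 1)), tolower(substring(tok, 2)))])
}

AA1_CLASS <- paste(AA1, collapse = "")
AA3_ALT <- paste(AA3, collapse = "|")

# One-letter wNm form requires a 2+ digit position so that gene-name
# lookalikes (H2A, T4, ...) are not picked up; three-letter and spelled-out
# "to" forms accept any position.
MUTATION_REGEXES <- c(
  one_letter = sprintf(
    "(?<![[:alnum:]])([%s])([1-9][0-9]+)([%s])(?![[:alnum:]])",
    AA1_CLASS, AA1_CLASS),
  three_letter = sprintf(
    "(?<![[:alnum:]])((?i:%s))[ -]?([1-9][0-9]*)[ -]?((?i:%s))(?![[:alnum:]])",
    AA3_ALT, AA3_ALT),
  to_form = sprintf(
    "(?<![[:alnum:]])((?i:%s)|[%s])([1-9][0-9]*) to ((?i:%s)|[%s])(?![[:alnum:]])",
    AA3_ALT, AA1_CLASS, AA3_ALT, AA1_CLASS)
)

#' Detect point-mutation mentions in a sentence
#'
#' Matches one-letter (`A123T`), three-letter (`Ala123Thr`) and spelled-out
#' (`Ala123 to Thr`, `A123 to T`) substitution forms and normalizes each to
#' the one-letter `wNm` representation. The bare one-letter form requires a
#' position of at least two digits, which keeps short gene-name lookalikes
#' (H2A, CD4-style tokens) out of the results. Wild-type and mutant residues
#' must both be valid one-letter amino-acid codes.
#'
#' @param sentence A single string.
#' @return Tibble with `raw_text`, `wild_type`, `position`, `mutant`,
#'   `normalized` (e.g. `"A123T"`), and 0-based half-open `start`/`end` spans.
#' @export
find_mutations <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  hits <- list()
  for (form in names(MUTATION_REGEXES)) {
    rx <- MUTATION_REGEXES[[form]]
    m <- gregexpr(rx, sentence, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      raw <- substring(sentence, starts[i], starts[i] + lens[i] - 1L)
      parts <- regmatches(raw, regexec(rx, raw, perl = TRUE))[[1]]
      wt <- aa_from_token(parts[2])
      mut <- aa_from_token(parts[4])
      if (is.na(wt) || is.na(mut)) next
      hits[[length(hits) + 1L]] <- tibble(
        raw_text = raw, wild_type = wt,
        position = as.integer(parts[3]), mutant = mut,
        normalized = sprintf("%s%s%s", wt, parts[3], mut),
        start = starts[i] - 1L, end = starts[i] + lens[i] - 1L,
        form = form
      )
    }
  }
  if (length(hits) == 0L) {
    return(tibble(raw_text = character(), wild_type = character(),
                  position = integer(), mutant = character(),
                  normalized = character(), start = integer(),
                  end = integer(), form = character()))
  }
  out <- dplyr::bind_rows(hits)
  # prefer the longest span when forms overlap (e.g. "Ala123 to Thr" also
  # nests no shorter hit, but "A123 to T" vs "A123T" cannot co-occur)
  out <- out[order(out$start, -(out$end - out$start)), ]
  keep <- logical(nrow(out))
  frontier <- -1L
  for (i in seq_len(nrow(out))) {
    if (out$start[i] > frontier) {
      keep[i] <- TRUE
      frontier <- out$end[i] - 1L
    }
  }
  out[keep, , drop = FALSE]
}

#' Default mutation-linking pattern table
#'
#' Priority-ranked textual patterns connecting a mutation mention to a
#' protein mention in the same sentence. Patterns are data, not code: the
#' table is read from the package's `extdata/mutation_patterns.tsv`, and a
#' user file in the same format may be supplied instead. Each row gives the
#' pattern id, its priority (lower fires first), the pattern type, a
#' connector regular expression applied to the text between the two mentions,
#' whether the pattern is enabled, and a human-readable template.
#'
#' Shipped patterns: (1) `protein - mutation`, (2) `mutation of/in protein`,
#' (3) `mutation for (the) protein`, (4) enumerated mutation lists
#' distributing over one protein (`mutations A, B and C for protein`), and
#' (5) a nearest-protein-within-5-tokens fallback, disabled by default
#' because it trades precision for recall.
#'
#' @param path Optional path to an alternative pattern TSV.
#' @return Tibble with columns `pattern_id`, `priority`, `type`, `connector`,
#'   `enabled`, `template`.
#' @export
mutation_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mutation_patterns.tsv",
                        package = "topicminer", mustWork = TRUE)
  }
  pat <- as_tibble(read.delim(path, stringsAsFactors = FALSE, quote = ""))
  stopifnot(all(c("pattern_id", "priority", "type", "connector", "enabled",
                  "template") %in% names(pat)))
  pat$enabled <- as.logical(pat$enabled)
  pat[order(pat$priority), ]
}

between_text <- function(sentence, left_end, right_start) {
  if (right_start <= left_end) return(NULL)
  substring(sentence, left_end + 1L, right_start)
}

token_distance <- function(sentence, span_a_start, span_b_start) {
  toks <- tokenize_spans(sentence)
  ia <- token_index_at(toks, span_a_start)
  ib <- token_index_at(toks, span_b_start)
  if (is.na(ia) || is.na(ib)) return(NA_integer_)
  abs(ia - ib)
}

#' Link mutation mentions to protein mentions within a sentence
#'
#' Applies the priority-ranked pattern table: patterns fire in priority
#' order, each mutation links to at most one protein, and the enumeration
#' pattern distributes a comma/`and`-separated run of mutations over a single
#' trailing protein. No link crosses a sentence boundary by construction.
#' Mutations no pattern can attach are returned unlinked -- the
#' precision-oriented contract is that a link is only ever emitted when a
#' pattern fires.
#'
#' @param sentence The sentence both mention sets refer to.
#' @param proteins Tibble (or list of `tm_participant`) with `mention_text`,
#'   `start`, `end` (0-based half-open spans in `sentence`).
#' @param mutations Tibble from [find_mutations()].
#' @param patterns Pattern table from [mutation_patterns()].
#' @return List with `links` (tibble: `protein`, `protein_start`,
#'   `mutation`, `mutation_start`, `pattern_id`) and `unlinked` (the rows of
#'   `mutations` left unattached).
#' @export
link_mutations <- function(sentence, proteins, mutations,
                           patterns = mutation_patterns()) {
  if (is.list(proteins) && !is.data.frame(proteins)) {
    proteins <- dplyr::bind_rows(lapply(proteins, function(p) {
      tibble(mention_text = p$mention_text, start = p$start, end = p$end)
    }))
  }
  links <- tibble(protein = character(), protein_start = integer(),
                  mutation = character(), mutation_start = integer(),
                  pattern_id = integer())
  if (nrow(mutations) == 0L) return(list(links = links, unlinked = mutations))
  linked <- rep(FALSE, nrow(mutations))
  if (nrow(proteins) > 0L) {
    for (pi in seq_len(nrow(patterns))) {
      pat <- patterns[pi, ]
      if (!pat$enabled) next
      for (mi in seq_len(nrow(mutations))) {
        if (linked[mi]) next
        hit <- switch(
          pat$type,
          protein_then_mutation = {
            gap <- vapply(seq_len(nrow(proteins)), function(k) {
              bt <- between_text(sentence, proteins$end[k], mutations$start[mi])
              !is.null(bt) && grepl(pat$connector, bt, perl = TRUE)
            }, TRUE)
            if (any(gap)) which(gap)[1] else NA_integer_
          },
          mutation_then_protein = {
            gap <- vapply(seq_len(nrow(proteins)), function(k) {
              bt <- between_text(sentence, mutations$end[mi], proteins$start[k])
              !is.null(bt) && grepl(pat$connector, bt, perl = TRUE)
            }, TRUE)
            if (any(gap)) which(gap)[1] else NA_integer_
          },
          enumeration_then_protein = {
            run <- enumeration_run(sentence, mutations, mi, linked)
            tail_mi <- run[length(run)]
            gap <- vapply(seq_len(nrow(proteins)), function(k) {
              bt <- between_text(sentence, mutations$end[tail_mi], proteins$start[k])
              !is.null(bt) && grepl(pat$connector, bt, perl = TRUE)
            }, TRUE)
            if (length(run) > 1L && any(gap)) {
              k <- which(gap)[1]
              for (r in run[!linked[run]]) {
                links <- dplyr::bind_rows(links, tibble(
                  protein = proteins$mention_text[k],
                  protein_start = proteins$start[k],
                  mutation = mutations$normalized[r],
                  mutation_start = mutations$start[r],
                  pattern_id = pat$pattern_id
                ))
                linked[r] <- TRUE
              }
            }
            NA_integer_
          },
          proximity = {
            d <- vapply(seq_len(nrow(proteins)), function(k) {
              token_distance(sentence, proteins$start[k], mutations$start[mi])
            }, 0L)
            ok <- which(!is.na(d) & d <= as.integer(pat$connector))
            if (length(ok) > 0L) ok[which.min(d[ok])] else NA_integer_
          },
          NA_integer_
        )
        if (!is.na(hit)) {
          links <- dplyr::bind_rows(links, tibble(
            protein = proteins$mention_text[hit],
            protein_start = proteins$start[hit],
            mutation = mutations$normalized[mi],
            mutation_start = mutations$start[mi],
            pattern_id = pat$pattern_id
          ))
          linked[mi] <- TRUE
        }
      }
    }
  }
  list(links = links, unlinked = mutations[!linked, , drop = FALSE])
}

# Maximal run of mutations starting at `mi` joined by "," / "and". Members
# already linked by a higher-priority pattern stay in the run (they anchor
# the trailing protein) but are not re-linked by the caller.
enumeration_run <- function(sentence, mutations, mi, linked) {
  ord <- order(mutations$start)
  pos <- which(ord == mi)
  run <- mi
  while (pos < length(ord)) {
    nxt <- ord[pos + 1L]
    bt <- between_text(sentence, mutations$end[run[length(run)]],
                       mutations$start[nxt])
    if (is.null(bt) || !grepl("^\\s*,\\s*(and\\s+)?$|^\\s+and\\s+$", bt)) break
    run <- c(run, nxt)
    pos <- pos + 1L
  }
  run
}
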