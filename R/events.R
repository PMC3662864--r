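GENIA_EVENT_TYPES <- c(
  "gene_expression", "transcription", "protein_catabolism", "phosphorylation",
  "localization", "binding", "regulation", "positive_regulation",
  "negative_regulation"
)
REGULATION_TYPES <- c("regulation", "positive_regulation", "negative_regulation")

#' Create an event participant
#'
#' A gene/protein/RNA mention taking part in an event. Participants may be
#' normalized to an Entrez Gene ID (and optionally a species taxon and a
#' homologene group); unnormalized participants are identified by their
#' surface text.
#'
#' @param mention_text Surface string of the mention.
#' @param start,end 0-based half-open character span within the sentence.
#' @param entrez_id,species_taxid,homologene_id Optional integer identifiers.
#' @param go_terms Character vector of GO ids (usually filled later by
#'   [annotate_go()]).
#' @param mutations List of mutation mentions linked to this participant.
#' @return A list of class `tm_participant`.
#' @export
participant <- function(mention_text, start = NA_integer_, end = NA_integer_,
                        entrez_id = NULL, species_taxid = NULL,
                        homologene_id = NULL, go_terms = character(),
                        mutations = list()) {
  if (!is.null(entrez_id)) {
    entrez_id <- as.integer(entrez_id)
    if (is.na(entrez_id) || entrez_id <= 0L) stopf("entrez_id must be positive")
  }
  structure(
    list(mention_text = mention_text, start = as.integer(start),
         end = as.integer(end), entrez_id = entrez_id,
         species_taxid = species_taxid, homologene_id = homologene_id,
         go_terms = go_terms, mutations = mutations),
    class = "tm_participant"
  )
}

#' Create an event node
#'
#' One molecular event of the nine GENIA types. Non-binding, non-regulatory
#' events take exactly one molecular theme; binding may take several; only
#' the three regulation types may have another event as theme, or any cause.
#'
#' @param event_type One of the nine GENIA event types.
#' @param themes Non-empty list of `tm_participant` or nested `tm_event`.
#' @param cause Optional `tm_participant` or `tm_event` (regulation only).
#' @param trigger_text,trigger_start,trigger_end The trigger word and its
#'   0-based half-open span within the sentence.
#' @return A list of class `tm_event`.
#' @export
event_node <- function(event_type, themes, cause = NULL,
                       trigger_text = "", trigger_start = NA_integer_,
                       trigger_end = NA_integer_) {
  if (!event_type %in% GENIA_EVENT_TYPES) {
    stopf("unknown event type %s", sQuote(event_type))
  }
  if (!is.list(themes) || length(themes) == 0L) stopf("themes must be non-empty")
  if (length(themes) > 1L && event_type != "binding") {
    stopf("only binding events may have more than one theme")
  }
  is_reg <- event_type %in% REGULATION_TYPES
  nested_theme <- any(vapply(themes, inherits, TRUE, what = "tm_event"))
  if (!is_reg && (nested_theme || !is.null(cause))) {
    stopf("only regulation-type events may nest an event theme or carry a cause")
  }
  node <- structure(
    list(event_type = event_type, themes = themes, cause = cause,
         trigger_text = trigger_text, trigger_start = as.integer(trigger_start),
         trigger_end = as.integer(trigger_end)),
    class = "tm_event"
  )
  if (event_depth(node) > 3L) stopf("event chains may nest at most three events")
  node
}

event_depth <- function(node) {
  if (inherits(node, "tm_participant")) return(0L)
  subs <- c(node$themes, if (!is.null(node$cause)) list(node$cause))
  1L + max(0L, vapply(subs, event_depth, 0L))
}

#' Create an event-chain mention
#'
#' One textual mention of a (possibly nested) event chain, originating from a
#' single sentence of a document, together with extractor-supplied context:
#' a confidence score, negation and speculation flags, and anatomy terms
#' mapped to the event.
#'
#' @param doc_id Source document id.
#' @param sentence_text The source sentence.
#' @param root The root `tm_event`.
#' @param section,paragraph_index,sentence_index Location of the sentence in
#'   the document (section name; 0-based paragraph index, body only; 0-based
#'   sentence index within the text unit).
#' @param confidence Extractor confidence in `[0, 1]`.
#' @param negated,speculated Logical flags.
#' @param anatomy_terms Character vector of anatomical mentions mapped to the
#'   event.
#' @return A list of class `tm_mention`.
#' @export
event_chain_mention <- function(doc_id, sentence_text, root,
                                section = "body", paragraph_index = NA_integer_,
                                sentence_index = 0L, confidence = NA_real_,
                                negated = FALSE, speculated = FALSE,
                                anatomy_terms = character()) {
  stopifnot(inherits(root, "tm_event"))
  if (!is.na(confidence) && (confidence < 0 || confidence > 1)) {
    stopf("confidence must lie in [0, 1]")
  }
  structure(
    list(doc_id = doc_id, sentence_text = sentence_text, root = root,
         section = section, paragraph_index = as.integer(paragraph_index),
         sentence_index = as.integer(sentence_index),
         confidence = as.numeric(confidence), negated = isTRUE(negated),
         speculated = isTRUE(speculated),
         anatomy_terms = as.character(anatomy_terms)),
    class = "tm_mention"
  )
}

participant_key <- function(p) {
  if (!is.null(p$entrez_id)) sprintf("G%d", p$entrez_id)
  else paste0("u:", tolower(p$mention_text))
}

# Sort key for binding themes: normalized participants first (ascending
# Entrez id), then unnormalized case-insensitive alphabetically.
order_binding_themes <- function(themes) {
  norm <- vapply(themes, function(t) {
    inherits(t, "tm_participant") && !is.null(t$entrez_id)
  }, TRUE)
  key1 <- ifelse(norm, 0L, 1L)
  key2 <- vapply(themes, function(t) {
    if (inherits(t, "tm_participant") && !is.null(t$entrez_id)) {
      sprintf("%012d", t$entrez_id)
    } else if (inherits(t, "tm_participant")) {
      tolower(t$mention_text)
    } else {
      node_signature(t)
    }
  }, "")
  themes[order(key1, key2, method = "radix")]
}

node_signature <- function(node) {
  if (inherits(node, "tm_participant")) return(participant_key(node))
  themes <- node$themes
  if (node$event_type == "binding" && length(themes) > 1L) {
    themes <- order_binding_themes(themes)
  }
  sig <- sprintf(
    "%s(%s%s)",
    node$event_type,
    paste(vapply(themes, node_signature, ""), collapse = "+"),
    if (is.null(node$cause)) "" else paste0(";cause=", node_signature(node$cause))
  )
  sig
}

#' Canonical signature of an event-chain mention
#'
#' Serializes the event tree into a deterministic string used as the grouping
#' key for identical interactions across sentences and documents. Participants
#' are identified by Entrez Gene ID when normalized (`G<id>`) and by
#' lowercased surface text tagged `u:` otherwise, so that grouping never
#' depends on surface gene symbols. Binding themes are order-free: they are
#' sorted ascending by Entrez id when all participants are normalized, and
#' case-insensitive alphabetically otherwise (normalized before unnormalized
#' in mixed bindings). Cause and theme of regulatory events are kept asymmetric.
#'
#' The serialization is a parenthesized prefix notation, e.g.
#' `positive_regulation(gene_expression(G2354);cause=G885)`, and is stable
#' across package versions: signatures are join keys.
#'
#' @param mention A `tm_mention` (or a bare `tm_event`).
#' @return A single string.
#' @export
canonical_signature <- function(mention) {
  root <- if (inherits(mention, "tm_mention")) mention$root else mention
  stopifnot(inherits(root, "tm_event"))
  node_signature(root)
}

collect_participants <- function(node) {
  if (inherits(node, "tm_participant")) return(list(node))
  subs <- c(node$themes, if (!is.null(node$cause)) list(node$cause))
  do.call(c, lapply(subs, collect_participants))
}

collect_event_types <- function(node) {
  if (inherits(node, "tm_participant")) return(character())
  subs <- c(node$themes, if (!is.null(node$cause)) list(node$cause))
  c(node$event_type, unlist(lapply(subs, collect_event_types)))
}

chain_class <- function(participant_count) {
  dplyr::case_when(
    participant_count <= 1L ~ "single_event",
    participant_count == 2L ~ "molecular_interaction",
    TRUE ~ "multi"
  )
}

#' Group event-chain mentions into unique interactions
#'
#' Mentions sharing a [canonical_signature()] are collapsed into one grouped
#' record carrying the total mention frequency, the number of distinct source
#' documents, the count of distinct molecule slots, the maximum extractor
#' confidence over members, and aggregate polarity/speculation calls. Groups
#' with exactly two distinct molecules are molecular interactions; one
#' molecule is a single event. Self-interactions (a binding of a gene with
#' itself) stay in the output but are flagged.
#'
#' @param mentions List of `tm_mention` objects.
#' @return A tibble ordered by descending frequency then signature, with
#'   columns `signature`, `class`, `participant_count`, `frequency`,
#'   `doc_count`, `confidence`, `polarity`, `speculation`, `self_interaction`,
#'   and a `mentions` list-column holding the member mentions.
#' @export
group_event_chains <- function(mentions) {
  if (length(mentions) == 0L) {
    return(tibble(
      signature = character(), class = character(), participant_count = integer(),
      frequency = integer(), doc_count = integer(), confidence = numeric(),
      polarity = character(), speculation = character(),
      self_interaction = logical(), mentions = list()
    ))
  }
  sigs <- vapply(mentions, canonical_signature, "")
  groups <- split(mentions, sigs)
  rows <- lapply(names(groups), function(sig) {
    mem <- groups[[sig]]
    parts <- collect_participants(mem[[1]]$root)
    keys <- vapply(parts, participant_key, "")
    pol <- classify_polarity(vapply(mem, function(m) m$negated, TRUE),
                             vapply(mem, function(m) m$speculated, TRUE))
    tibble(
      signature = sig,
      participant_count = length(unique(keys)),
      frequency = length(mem),
      doc_count = length(unique(vapply(mem, function(m) m$doc_id, ""))),
      confidence = suppressWarnings(max(vapply(mem, function(m) m$confidence, 0))),
      polarity = pol$polarity,
      speculation = pol$speculation,
      self_interaction = length(keys) > 1L && length(unique(keys)) == 1L,
      mentions = list(mem)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$class <- chain_class(out$participant_count)
  out <- out[order(-out$frequency, out$signature, method = "radix"), ]
  out[, c("signature", "class", "participant_count", "frequency", "doc_count",
          "confidence", "polarity", "speculation", "self_interaction",
          "mentions")]
}

#' Aggregate polarity and speculation over a group's mentions
#'
#' A grouped chain is `all_negative` iff every mention is negated,
#' `all_positive` iff none is, and `mixed` otherwise (some mentions reported
#' negatively and others positively -- a potential contradiction in the
#' literature). Speculation aggregates analogously to `none`/`all`/`mixed`.
#'
#' @param negated,speculated Logical vectors over a group's mentions.
#' @return List with `polarity` and `speculation` strings.
#' @export
classify_polarity <- function(negated, speculated) {
  if (length(negated) == 0L) stopf("group must contain at least one mention")
  polarity <- if (all(negated)) "all_negative"
    else if (!any(negated)) "all_positive" else "mixed"
  speculation <- if (all(speculated)) "all"
    else if (!any(speculated)) "none" else "mixed"
  list(polarity = polarity, speculation = speculation)
}

#' Attach GO terms to normalized participants
#'
#' Joins each normalized participant's Entrez id against a gene2go-style
#' mapping, taking the union of its GO ids and (optionally) their GO Slim
#' ancestors. Unnormalized participants are untouched.
#'
#' @param groups Grouped tibble from [group_event_chains()].
#' @param gene2go Data frame with columns `entrez_id`, `go_id`.
#' @param goslim Optional named character vector mapping GO id to slim id.
#' @return `groups` with participant `go_terms` filled in place.
#' @export
annotate_go <- function(groups, gene2go, goslim = NULL) {
  stopifnot(all(c("entrez_id", "go_id") %in% names(gene2go)))
  lookup <- split(gene2go$go_id, gene2go$entrez_id)
  fill_node <- function(node) {
    if (inherits(node, "tm_participant")) {
      if (!is.null(node$entrez_id)) {
        gos <- lookup[[as.character(node$entrez_id)]] %||% character()
        slims <- if (!is.null(goslim)) unname(goslim[gos]) else character()
        node$go_terms <- sort(unique(c(gos, slims[!is.na(slims)])))
      }
      return(node)
    }
    node$themes <- lapply(node$themes, fill_node)
    if (!is.null(node$cause)) node$cause <- fill_node(node$cause)
    node
  }
  groups$mentions <- lapply(groups$mentions, function(mem) {
    lapply(mem, function(m) { m$root <- fill_node(m$root); m })
  })
  groups
}

#' Context frequency tables over grouped event chains
#'
#' Tabulates (i) anatomy terms over all member mentions and (ii) event types
#' by chain class. Event-type counts come in two flavours: `non_redundant`
#' counts each group once per event type present anywhere in its chain, while
#' `total` counts repeated occurrences within a chain (a positive regulation
#' of a positive regulation contributes two to its total).
#'
#' @param groups Grouped tibble from [group_event_chains()].
#' @return List with `anatomy` (tibble: `term`, `mentions`) and
#'   `event_types` (tibble: `event_type`, `class`, `non_redundant`, `total`).
#' @export
summarize_context <- function(groups) {
  if (nrow(groups) == 0L) {
    return(list(
      anatomy = tibble(term = character(), mentions = integer()),
      event_types = tibble(event_type = character(), class = character(),
                           non_redundant = integer(), total = integer())
    ))
  }
  anat <- unlist(lapply(groups$mentions, function(mem) {
    unlist(lapply(mem, function(m) m$anatomy_terms))
  }))
  anatomy <- if (length(anat) > 0L) {
    tab <- sort(table(anat), decreasing = TRUE)
    tibble(term = names(tab), mentions = as.integer(tab))
  } else {
    tibble(term = character(), mentions = integer())
  }
  type_rows <- lapply(seq_len(nrow(groups)), function(i) {
    types <- collect_event_types(groups$mentions[[i]][[1]]$root)
    tab <- table(types)
    tibble(event_type = names(tab), class = groups$class[i],
           non_redundant = 1L, total = as.integer(tab))
  })
  event_types <- dplyr::bind_rows(type_rows) |>
    dplyr::group_by(.data$event_type, .data$class) |>
    dplyr::summarise(
      non_redundant = sum(.data$non_redundant),
      total = sum(.data$total), .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$non_redundant))
  list(anatomy = anatomy, event_types = event_types)
}

# ---- JSON serialization of event mentions --------------------------------

node_to_list <- function(node) {
  na_null <- function(x) if (length(x) == 1L && is.na(x)) NULL else x
  if (inherits(node, "tm_participant")) {
    out <- list(kind = "participant", mention_text = node$mention_text,
                start = na_null(node$start), end = na_null(node$end))
    for (f in c("entrez_id", "species_taxid", "homologene_id")) {
      if (!is.null(node[[f]])) out[[f]] <- node[[f]]
    }
    if (length(node$go_terms) > 0L) out$go_terms <- as.list(node$go_terms)
    return(out)
  }
  list(
    kind = "event", event_type = node$event_type,
    trigger = list(text = node$trigger_text, start = na_null(node$trigger_start),
                   end = na_null(node$trigger_end)),
    themes = lapply(node$themes, node_to_list),
    cause = if (is.null(node$cause)) NULL else node_to_list(node$cause)
  )
}

node_from_list <- function(x) {
  if (identical(x$kind, "participant")) {
    return(participant(
      mention_text = x$mention_text, start = x$start %||% NA_integer_,
      end = x$end %||% NA_integer_, entrez_id = x$entrez_id,
      species_taxid = x$species_taxid, homologene_id = x$homologene_id,
      go_terms = as.character(unlist(x$go_terms))
    ))
  }
  event_node(
    event_type = x$event_type,
    themes = lapply(x$themes, node_from_list),
    cause = if (is.null(x$cause)) NULL else node_from_list(x$cause),
    trigger_text = x$trigger$text %||% "",
    trigger_start = x$trigger$start %||% NA_integer_,
    trigger_end = x$trigger$end %||% NA_integer_
  )
}

#' Read event-chain mentions from JSON
#'
#' The file holds a JSON array of mention objects mirroring a flattened
#' event-extractor export: document id, sentence text and location, a nested
#' `root` event (participants with optional Entrez/species/homologene ids),
#' confidence, negation/speculation flags, and anatomy terms.
#'
#' @param path Path to a JSON file.
#' @return List of `tm_mention` objects.
#' @export
read_event_mentions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    event_chain_mention(
      doc_id = x$doc_id, sentence_text = x$sentence_text,
      root = node_from_list(x$root),
      section = x$section %||% "body",
      paragraph_index = x$paragraph_index %||% NA_integer_,
      sentence_index = x$sentence_index %||% 0L,
      confidence = x$confidence %||% NA_real_,
      negated = isTRUE(x$negated), speculated = isTRUE(x$speculated),
      anatomy_terms = as.character(unlist(x$anatomy_terms))
    )
  })
}

#' Write event-chain mentions to JSON
#'
#' @param mentions List of `tm_mention` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_mentions <- function(mentions, path) {
  drop_na <- function(x) if (length(x) == 1L && is.na(x)) NULL else x
  out <- lapply(mentions, function(m) {
    list(
      doc_id = m$doc_id, sentence_text = m$sentence_text,
      section = m$section, paragraph_index = drop_na(m$paragraph_index),
      sentence_index = m$sentence_index, confidence = drop_na(m$confidence),
      negated = m$negated, speculated = m$speculated,
      anatomy_terms = as.list(m$anatomy_terms),
      root = node_to_list(m$root)
    )
  })
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, null = "null",
                              digits = NA), path)
  invisible(path)
}

#' Write grouped event chains as TSV
#'
#' Flat export of [group_event_chains()] output (without the mention
#' structures, which live in the JSON export).
#'
#' @param groups Grouped tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  flat <- groups[, setdiff(names(groups), "mentions")]
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
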