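#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; see [run_pipeline()] for recognised keys.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

plog <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full catalogue-building pipeline
#'
#' Orchestrates the stages in dependency order: load lexicons, build the
#' topic corpus (retrieval by specific terms, relevance scoring), read and
#' filter event mentions to retained documents, group them into unique
#' interactions, annotate GO terms, summarize context, score term-to-event
#' relevancy and aggregate per group, and -- when gold genes, background
#' events or curation labels are supplied -- compute the enrichment and
#' curation statistics. Each stage's outputs are written before the next
#' starts, so any intermediate can be inspected or replaced; a stage failure
#' aborts with an error naming the stage. Reruns with identical inputs
#' produce identical outputs.
#'
#' @param config Named list (or path to a YAML file) with entries: `lexicon`,
#'   `documents`, `events` (paths, required); `disease_lexicon`, `gene2go`,
#'   `gold_genes`, `background_events`, `curation_labels` (paths, optional);
#'   `section_weights` (named list), `confidence_cutoff` (default 0.5),
#'   `seed` (default 1).
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage count logging.
#' @return Invisibly, a list with the main in-memory results (`corpus`,
#'   `groups`, `relevancy`, `stats`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  for (key in c("lexicon", "documents", "events")) {
    if (is.null(config[[key]])) stopf("config lacks required path '%s'", key)
    if (!file.exists(config[[key]])) {
      stopf("stage 'inputs' failed: %s file not found: %s", key, config[[key]])
    }
  }
  for (key in c("disease_lexicon", "gene2go", "gold_genes",
                "background_events", "curation_labels")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stopf("stage 'inputs' failed: %s file not found: %s", key, config[[key]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- if (!is.null(config$section_weights)) {
    unlist(config$section_weights)
  } else {
    default_section_weights()
  }

  lex <- pipeline_stage("lexicon", load_lexicon(config$lexicon))
  plog(quiet, "lexicon: %d terms, %d synonyms",
       nrow(lex$entries), length(lex$index))

  corpus <- pipeline_stage("corpus", {
    docs <- read_documents(config$documents)
    build_corpus(docs, lex, section_weights = weights)
  })
  utils::write.table(corpus$scores, file.path(out_dir, "corpus_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$matches, file.path(out_dir, "term_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  plog(quiet, "corpus: %d documents retained, %d term matches",
       length(corpus$documents), nrow(corpus$matches))

  retained_ids <- vapply(corpus$documents, function(d) d$doc_id, "")
  groups <- pipeline_stage("events", {
    mentions <- read_event_mentions(config$events)
    mentions <- Filter(function(m) m$doc_id %in% retained_ids, mentions)
    group_event_chains(mentions)
  })
  if (!is.null(config$gene2go)) {
    groups <- pipeline_stage("annotate_go", {
      g2g <- read.delim(config$gene2go, stringsAsFactors = FALSE)
      annotate_go(groups, g2g)
    })
  }
  write_groups(groups, file.path(out_dir, "groups.tsv"))
  ctx <- summarize_context(groups)
  utils::write.table(ctx$anatomy, file.path(out_dir, "anatomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ctx$event_types, file.path(out_dir, "event_types.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  plog(quiet, "events: %d mentions grouped into %d unique chains (%d interactions)",
       sum(groups$frequency), nrow(groups),
       sum(groups$class == "molecular_interaction"))

  relevancy <- pipeline_stage("relevancy", {
    score_group_relevancy(groups, corpus, lex)
  })
  utils::write.table(relevancy, file.path(out_dir, "relevancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  plog(quiet, "relevancy: %d groups scored (%d high, %d medium)",
       nrow(relevancy), sum(relevancy$band == "high"),
       sum(relevancy$band == "medium"))

  stats <- list()
  if (!is.null(config$gold_genes) && !is.null(config$background_events)) {
    stats$enrichment <- pipeline_stage("enrichment", {
      gold <- as.integer(readLines(config$gold_genes))
      mentions <- read_event_mentions(config$events)
      mentions <- Filter(function(m) m$doc_id %in% retained_ids, mentions)
      bg <- read_event_mentions(config$background_events)
      gst <- gene_set_table(mentions, bg, gold)
      fe <- fisher_enrichment(gst$counts$a, gst$counts$b,
                              gst$counts$c, gst$counts$d)
      list(table = gst$table, odds_ratio = fe$odds_ratio,
           p_value = fe$p_value, p_display = fe$p_display)
    })
    plog(quiet, "enrichment: OR %.3f (p %s)",
         stats$enrichment$odds_ratio, stats$enrichment$p_display)
  }
  if (!is.null(config$curation_labels)) {
    stats$curation <- pipeline_stage("curation_stats", {
      rec <- read_curation_labels(config$curation_labels)
      cutoff <- config$confidence_cutoff %||% 0.5
      strata <- precision_by_strata(rec, cutoff)
      triage <- tryCatch(fit_triage_model(rec), error = function(e) NULL)
      list(strata = strata, triage = triage)
    })
    plog(quiet, "curation: overall precision %.2f%%",
         stats$curation$strata$overall)
  }
  report <- c(
    sprintf("documents_retained\t%d", length(corpus$documents)),
    sprintf("term_matches\t%d", nrow(corpus$matches)),
    sprintf("unique_event_chains\t%d", nrow(groups)),
    sprintf("molecular_interactions\t%d",
            sum(groups$class == "molecular_interaction")),
    if (!is.null(stats$enrichment)) {
      sprintf("gold_gene_odds_ratio\t%.6f", stats$enrichment$odds_ratio)
    },
    if (!is.null(stats$curation)) {
      sprintf("curation_precision_overall\t%.4f", stats$curation$strata$overall)
    }
  )
  writeLines(report, file.path(out_dir, "run_summary.tsv"))
  invisible(list(corpus = corpus, groups = groups, relevancy = relevancy,
                 stats = stats, out_dir = out_dir))
}

#' Score overall relevancy for every group in a corpus
#'
#' Convenience wrapper joining corpus term matches to grouped event chains:
#' computes the term-to-mention relevancy links for every (term match,
#' mention) pair sharing a document, then aggregates per group with
#' [overall_relevancy()].
#'
#' @param groups Grouped tibble from [group_event_chains()].
#' @param corpus Result of [build_corpus()].
#' @param lexicon The `topic_lexicon` used to build the corpus, or `NULL`
#'   for unweighted aggregation.
#' @param matches Optional match tibble to use instead of `corpus$matches`
#'   (e.g. disease-term matches).
#' @return Tibble: `signature`, `score`, `band`.
#' @export
score_group_relevancy <- function(groups, corpus, lexicon = NULL,
                                  matches = NULL) {
  matches <- matches %||% corpus$matches
  doc_lookup <- setNames(corpus$documents,
                         vapply(corpus$documents, function(d) d$doc_id, ""))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    mem <- groups$mentions[[i]]
    links <- list()
    for (m in mem) {
      dm <- matches[matches$doc_id == m$doc_id, , drop = FALSE]
      if (nrow(dm) == 0L) next
      doc <- doc_lookup[[m$doc_id]]
      for (k in seq_len(nrow(dm))) {
        lk <- term_event_relevancy(dm[k, ], m, doc)
        lk$doc_id <- m$doc_id
        links[[length(links) + 1L]] <- lk
      }
    }
    links <- if (length(links) > 0L) dplyr::bind_rows(links) else {
      tibble(term_id = character(), score = numeric(), doc_id = character())
    }
    ov <- overall_relevancy(groups[i, ], links, lexicon)
    tibble(signature = groups$signature[i], score = ov$score, band = ov$band)
  })
  dplyr::bind_rows(rows)
}
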