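#' Configuration for the synthetic corpus generator
#'
#' Defines the statistical structure of a generated fixture bundle:
#' documents with sectioned text and planted dictionary terms, event-chain
#' mentions with normalized participants, gold-gene enrichment between a
#' focus and a background corpus, mutation sentences, and curation labels
#' whose confidence scores follow two beta distributions -- means 0.3 for
#' true and 0.1 for false interactions, the separation observed between
#' curated true and false positives in extractor output.
#'
#' All rates are probabilities in `[0, 1]`; planted term counts are placed
#' exactly (`round(rate * n_docs)` documents per section), never
#' sampled-then-lost. The seed is mandatory: a bundle is a pure function of
#' its configuration.
#'
#' @param n_docs Number of documents.
#' @param full_text_fraction Fraction of documents with body text (PMC-style).
#' @param specific_rates,relevant_rates Named per-section planting rates
#'   (`title`, `abstract`, `mesh`, `body`) for specific / relevant terms.
#' @param n_specific_terms,n_relevant_terms,n_disease_terms Lexicon sizes.
#' @param n_genes,gene_id_base Size and Entrez-id origin of the gene pool.
#' @param n_gold_genes Number of gold-set genes.
#' @param gold_enrichment Odds multiplier for a focus chain mentioning a
#'   gold gene, relative to background.
#' @param background_hit_rate Probability a background chain mentions a gold
#'   gene.
#' @param n_interactions,n_single_events Unique two-participant interaction
#'   templates and single-event templates in the focus corpus.
#' @param n_background_chains Unique chain templates in the background
#'   corpus.
#' @param true_fraction Fraction of interaction templates labelled true.
#' @param mean_mentions Mean mentions per template (1 + Poisson).
#' @param binding_fraction Fraction of interactions that are bindings (the
#'   rest are regulations, some nested).
#' @param unnormalized_rate Probability a non-gold participant lacks an
#'   Entrez id.
#' @param negation_rate,speculation_rate Per-mention context flag rates.
#' @param mutation_sentence_rate Fraction of focus mentions carrying a point
#'   mutation in their sentence.
#' @param mutation_linkable_fraction Fraction of mutation sentences phrased
#'   so that a linking pattern applies.
#' @param true_confidence_shape,false_confidence_shape Beta shape pairs for
#'   mention confidences of true / false templates.
#' @param seed Integer seed (required).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_docs = 80,
                       full_text_fraction = 0.5,
                       specific_rates = c(title = 0.4, abstract = 0.6,
                                          mesh = 0.3, body = 0.3),
                       relevant_rates = c(title = 0.1, abstract = 0.4,
                                          mesh = 0.2, body = 0.3),
                       n_specific_terms = 10, n_relevant_terms = 10,
                       n_disease_terms = 8,
                       n_genes = 60, gene_id_base = 1000L,
                       n_gold_genes = 12,
                       gold_enrichment = 2,
                       background_hit_rate = 0.15,
                       n_interactions = 30, n_single_events = 12,
                       n_background_chains = 40,
                       true_fraction = 0.5,
                       mean_mentions = 2.5,
                       binding_fraction = 0.5,
                       unnormalized_rate = 0.1,
                       negation_rate = 0.1, speculation_rate = 0.05,
                       mutation_sentence_rate = 0.15,
                       mutation_linkable_fraction = 0.8,
                       true_confidence_shape = c(1.5, 3.5),
                       false_confidence_shape = c(1, 9),
                       seed) {
  if (missing(seed) || !is_count(seed)) stopf("an integer seed is required")
  cfg <- as.list(environment())
  rates <- c(full_text_fraction, specific_rates, relevant_rates, true_fraction,
             background_hit_rate, binding_fraction, unnormalized_rate,
             negation_rate, speculation_rate, mutation_sentence_rate,
             mutation_linkable_fraction)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0, 1]")
  for (r in list(specific_rates, relevant_rates)) {
    if (!all(c("title", "abstract", "mesh", "body") %in% names(r))) {
      stopf("planting rates need title/abstract/mesh/body entries")
    }
  }
  if (n_gold_genes > n_genes) stopf("n_gold_genes cannot exceed n_genes")
  if (gold_enrichment <= 0) stopf("gold_enrichment must be positive")
  odds <- gold_enrichment * background_hit_rate / (1 - background_hit_rate)
  cfg$focus_hit_rate <- odds / (1 + odds)
  if (mean_mentions < 1) stopf("mean_mentions must be at least 1")
  structure(cfg, class = "sim_config")
}

FILLER_WORDS <- c(
  "the", "observed", "responses", "in", "treated", "samples", "showed",
  "consistent", "variation", "across", "replicates", "and", "conditions",
  "baseline", "measurements", "remained", "stable", "during", "follow",
  "up", "assessment", "of", "tissue", "preparations", "revealed", "uniform",
  "profiles", "overall", "findings", "support", "further", "analysis"
)

filler_sentence <- function(n_words = sample(6:12, 1)) {
  words <- sample(FILLER_WORDS, n_words, replace = TRUE)
  words[1] <- paste0(toupper(substring(words[1], 1, 1)), substring(words[1], 2))
  paste0(paste(words, collapse = " "), ".")
}

ANATOMY_POOL <- c("neurons", "spinal cord", "plasma", "brain", "liver",
                  "dorsal root ganglion", "macrophage", "nerve")

make_sim_lexicon_tsv <- function(prefix, abbrev, n, specificity, categories) {
  if (n == 0L) return(NULL)
  i <- seq_len(n)
  data.frame(
    term_id = sprintf("%s%03d", toupper(abbrev), i),
    name = sprintf("%s%02d", prefix, i),
    category = categories[((i - 1L) %% length(categories)) + 1L],
    specificity = specificity,
    synonyms = sprintf("%s%02d|%s%02dx", prefix, i, toupper(abbrev), i),
    stringsAsFactors = FALSE
  )
}

# Assemble a sentence from parts, recording 0-based half-open spans per part.
mk_sentence <- function(parts) {
  text <- ""
  spans <- list()
  for (p in parts) {
    start <- nchar(text)
    text <- paste0(text, p$text)
    if (!is.null(p$role)) {
      spans[[length(spans) + 1L]] <- tibble(
        role = p$role, text = p$text, start = start,
        end = start + nchar(p$text)
      )
    }
  }
  list(text = text, spans = spans_df <- dplyr::bind_rows(spans))
}

sample_mentions_count <- function(mean_mentions) 1L + rpois(1L, mean_mentions - 1)

# Sentence part lists per chain shape. Roles: p1/p2 (binding themes),
# cause/theme (regulations), trigger/trigger2, mutation.
chain_parts <- function(tpl, g) {
  tail_part <- list(text = paste0(" in ", tpl$anatomy, "."))
  switch(tpl$shape,
    binding = list(
      list(text = g[[1]]$symbol, role = "p1"),
      list(text = " "),
      list(text = "binds", role = "trigger"),
      list(text = " "),
      list(text = g[[2]]$symbol, role = "p2"),
      tail_part
    ),
    regulation = list(
      list(text = g[[1]]$symbol, role = "cause"),
      list(text = " "),
      list(text = switch(tpl$event_type,
                         positive_regulation = "augments",
                         negative_regulation = "suppresses", "modulates"),
           role = "trigger"),
      list(text = " "),
      list(text = g[[2]]$symbol, role = "theme"),
      tail_part
    ),
    nested_regulation = list(
      list(text = g[[1]]$symbol, role = "cause"),
      list(text = " "),
      list(text = "augments", role = "trigger"),
      list(text = " the "),
      list(text = "expression", role = "trigger2"),
      list(text = " of "),
      list(text = g[[2]]$symbol, role = "theme"),
      tail_part
    ),
    single = list(
      list(text = g[[1]]$symbol, role = "theme"),
      list(text = " is "),
      list(text = "expressed", role = "trigger"),
      tail_part
    )
  )
}

# Build one mention (sentence text + event tree + spans) for a chain
# template. A linkable mutation is spliced directly after the first
# participant ("GENEx - A45T ..."), so the shipped protein-hyphen-mutation
# pattern applies; an unlinkable one trails at the end of the sentence with
# no pattern in range.
build_chain_mention <- function(tpl, swap = FALSE, mutation = NULL) {
  g <- tpl$genes
  if (swap && length(g) == 2L && tpl$shape == "binding") g <- rev(g)
  parts <- chain_parts(tpl, g)
  if (!is.null(mutation)) {
    first_gene <- which(vapply(parts, function(p) {
      !is.null(p$role) && p$role %in% c("p1", "cause", "theme")
    }, TRUE))[1]
    if (mutation$linkable) {
      parts <- append(parts, list(
        list(text = " - "),
        list(text = mutation$normalized, role = "mutation")
      ), after = first_gene)
    } else {
      last <- parts[[length(parts)]]
      last$text <- sub("\\.$", "", last$text)
      parts <- c(parts[-length(parts)], list(
        last,
        list(text = ", whereas "),
        list(text = mutation$normalized, role = "mutation"),
        list(text = " remains uncharacterized.")
      ))
    }
  }
  s <- mk_sentence(parts)
  sp <- s$spans
  span_of <- function(role) sp[sp$role == role, ][1, ]
  mk_part <- function(gene, role) {
    r <- span_of(role)
    participant(gene$symbol, start = r$start, end = r$end,
                entrez_id = gene$entrez_id, species_taxid = gene$taxid,
                homologene_id = gene$homologene)
  }
  trig <- span_of("trigger")
  root <- switch(tpl$shape,
    binding = event_node(
      "binding", list(mk_part(g[[1]], "p1"), mk_part(g[[2]], "p2")),
      trigger_text = trig$text, trigger_start = trig$start,
      trigger_end = trig$end
    ),
    regulation = event_node(
      tpl$event_type, themes = list(mk_part(g[[2]], "theme")),
      cause = mk_part(g[[1]], "cause"),
      trigger_text = trig$text, trigger_start = trig$start,
      trigger_end = trig$end
    ),
    nested_regulation = {
      trig2 <- span_of("trigger2")
      inner <- event_node(
        "gene_expression", themes = list(mk_part(g[[2]], "theme")),
        trigger_text = trig2$text, trigger_start = trig2$start,
        trigger_end = trig2$end
      )
      event_node(
        "positive_regulation", themes = list(inner),
        cause = mk_part(g[[1]], "cause"),
        trigger_text = trig$text, trigger_start = trig$start,
        trigger_end = trig$end
      )
    },
    single = event_node(
      "gene_expression", themes = list(mk_part(g[[1]], "theme")),
      trigger_text = trig$text, trigger_start = trig$start,
      trigger_end = trig$end
    )
  )
  out <- list(text = s$text, root = root, spans = sp, anatomy = tpl$anatomy)
  if (!is.null(mutation)) {
    msp <- span_of("mutation")
    first_gene_role <- if (tpl$shape == "binding") "p1"
      else if (tpl$shape == "single") "theme" else "cause"
    fg <- span_of(first_gene_role)
    out$mutation <- tibble(
      normalized = mutation$normalized, start = msp$start, end = msp$end,
      linkable = mutation$linkable,
      protein = if (mutation$linkable) fg$text else NA_character_,
      protein_span_start = fg$start, protein_span_end = fg$end
    )
  }
  out
}

random_mutation <- function(linkable) {
  wt <- sample(AA1, 1)
  mut <- sample(setdiff(AA1, wt), 1)
  list(normalized = sprintf("%s%d%s", wt, sample(20:99, 1), mut),
       linkable = linkable)
}

new_gene_pool <- function(cfg) {
  ids <- cfg$gene_id_base + seq_len(cfg$n_genes) - 1L
  taxa <- sample(c(9606L, 10090L, 10116L), cfg$n_genes, replace = TRUE)
  pool <- lapply(seq_len(cfg$n_genes), function(i) {
    list(entrez_id = ids[i], symbol = sprintf("GENE%d", ids[i]),
         taxid = taxa[i], homologene = 500L + (ids[i] %% 97L))
  })
  gold <- sort(sample(ids, cfg$n_gold_genes))
  list(pool = pool, ids = ids, gold = gold)
}

sample_gene <- function(genes, gold_hit, cfg, exclude = integer()) {
  candidates <- if (gold_hit) {
    Filter(function(g) g$entrez_id %in% genes$gold &&
             !g$entrez_id %in% exclude, genes$pool)
  } else {
    Filter(function(g) !g$entrez_id %in% genes$gold &&
             !g$entrez_id %in% exclude, genes$pool)
  }
  g <- candidates[[sample.int(length(candidates), 1)]]
  if (!gold_hit && runif(1) < cfg$unnormalized_rate) {
    g <- list(entrez_id = NULL, symbol = tolower(g$symbol),
              taxid = NULL, homologene = NULL)
  }
  g
}

tpl_key <- function(shape, event_type, genes) {
  gk <- vapply(genes, function(g) {
    if (is.null(g$entrez_id)) paste0("u:", g$mention_text %||% g$symbol)
    else sprintf("G%d", g$entrez_id)
  }, "")
  if (shape == "binding") gk <- sort(gk)
  paste(shape, event_type, paste(gk, collapse = "|"))
}

make_chain_templates <- function(cfg, genes, n_two, n_single, hit_rate,
                                 id_prefix) {
  tpls <- list()
  seen <- character()
  for (i in seq_len(n_two)) {
    for (try in 1:100) {
      hit <- runif(1) < hit_rate
      g1 <- sample_gene(genes, hit, cfg)
      g2 <- sample_gene(genes, FALSE, cfg,
                        exclude = if (is.null(g1$entrez_id)) integer() else g1$entrez_id)
      shape <- if (runif(1) < cfg$binding_fraction) "binding"
        else sample(c("regulation", "nested_regulation"), 1, prob = c(0.7, 0.3))
      event_type <- if (shape == "regulation") {
        sample(REGULATION_TYPES, 1)
      } else NA_character_
      key <- tpl_key(shape, event_type, list(g1, g2))
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    tpls[[length(tpls) + 1L]] <- list(
      chain_id = sprintf("%s%03d", id_prefix, i), shape = shape,
      event_type = event_type, genes = list(g1, g2),
      gold_hit = hit,
      anatomy = sample(ANATOMY_POOL, 1),
      label = if (runif(1) < cfg$true_fraction) "tp" else "fp"
    )
  }
  for (i in seq_len(n_single)) {
    for (try in 1:100) {
      hit <- runif(1) < hit_rate
      g1 <- sample_gene(genes, hit, cfg)
      key <- tpl_key("single", "gene_expression", list(g1))
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    tpls[[length(tpls) + 1L]] <- list(
      chain_id = sprintf("%sS%03d", id_prefix, i), shape = "single",
      event_type = "gene_expression", genes = list(g1),
      gold_hit = hit, anatomy = sample(ANATOMY_POOL, 1),
      label = if (runif(1) < cfg$true_fraction) "tp" else "fp"
    )
  }
  tpls
}

#' Generate a synthetic fixture bundle
#'
#' Writes a complete, internally consistent input set for the pipeline:
#' `lexicon.tsv`, `disease_lexicon.tsv`, `documents.jsonl`, `events.json`
#' (focus corpus), `background_events.json`, `gold_genes.txt`, `gene2go.tsv`,
#' `curation_labels.tsv`, and `manifest.json` recording every planted ground
#' truth (term plantings, retained-document set, chain signatures with
#' expected frequencies and document counts, mutation links). Byte-identical
#' output for identical configuration; sentences are template-generated --
#' structural realism (sections, offsets, nesting, context flags), not
#' linguistic realism, is the goal.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the manifest.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, generate_bundle_impl(config, out_dir))
}

generate_bundle_impl <- function(cfg, out_dir) {
  paths <- list(
    lexicon = file.path(out_dir, "lexicon.tsv"),
    disease_lexicon = file.path(out_dir, "disease_lexicon.tsv"),
    documents = file.path(out_dir, "documents.jsonl"),
    events = file.path(out_dir, "events.json"),
    background_events = file.path(out_dir, "background_events.json"),
    gold_genes = file.path(out_dir, "gold_genes.txt"),
    gene2go = file.path(out_dir, "gene2go.tsv"),
    curation_labels = file.path(out_dir, "curation_labels.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  categories <- default_term_categories()

  lex_df <- rbind(
    make_sim_lexicon_tsv("algesium", "spt", cfg$n_specific_terms, "specific",
                         categories),
    make_sim_lexicon_tsv("nocivar", "rlt", cfg$n_relevant_terms, "relevant",
                         categories)
  )
  write.table(lex_df, paths$lexicon, sep = "\t", quote = FALSE, row.names = FALSE)
  dis_df <- make_sim_lexicon_tsv("morbidex", "dst", cfg$n_disease_terms,
                                 "relevant", categories)
  write.table(dis_df, paths$disease_lexicon, sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- documents with planted terms -------------------------------------
  n <- cfg$n_docs
  full_text <- seq_len(n) <= round(cfg$full_text_fraction * n)
  doc_ids <- sprintf("DOC%04d", seq_len(n))
  docs <- lapply(seq_len(n), function(i) {
    list(
      doc_id = doc_ids[i],
      title = filler_sentence(sample(5:8, 1)),
      abstract_sentences = replicate(sample(2:3, 1), filler_sentence()),
      mesh = tibble(
        descriptor = paste("Cohort", sample(c("Studies", "Analysis", "Review"), 1)),
        is_major = sample(c(TRUE, FALSE), 1)
      ),
      body = if (full_text[i]) {
        replicate(sample(2:3, 1),
                  paste(replicate(sample(2:3, 1), filler_sentence()),
                        collapse = " "),
                  simplify = TRUE)
      } else character(),
      source = if (full_text[i]) "pmc" else "medline"
    )
  })
  names(docs) <- doc_ids

  planted <- list()
  plant <- function(spec, section, rate) {
    eligible <- if (section == "body") doc_ids[full_text] else doc_ids
    n_plant <- round(rate * length(if (section == "body") doc_ids[full_text] else doc_ids))
    if (n_plant == 0L) return()
    targets <- sample(eligible, min(n_plant, length(eligible)))
    rows <- lex_df[lex_df$specificity == spec, ]
    for (d in targets) {
      row <- rows[sample.int(nrow(rows), 1), ]
      syn <- sample(strsplit(row$synonyms, "|", fixed = TRUE)[[1]], 1)
      if (section == "title") {
        # a second planting appends rather than overwriting the first
        docs[[d]]$title <<- if (isTRUE(docs[[d]]$title_planted)) {
          paste(docs[[d]]$title,
                sprintf("Considerations regarding %s apply.", syn))
        } else {
          sprintf("Effects of %s on measured responses.", syn)
        }
        docs[[d]]$title_planted <<- TRUE
      } else if (section == "abstract") {
        docs[[d]]$abstract_sentences <<- c(
          docs[[d]]$abstract_sentences,
          sprintf("This study examines %s closely.", syn)
        )
      } else if (section == "mesh") {
        docs[[d]]$mesh <<- dplyr::bind_rows(
          docs[[d]]$mesh,
          tibble(descriptor = syn, is_major = sample(c(TRUE, FALSE), 1))
        )
      } else {
        p <- sample.int(length(docs[[d]]$body), 1)
        docs[[d]]$body[p] <<- paste(
          docs[[d]]$body[p],
          sprintf("Additional context involves %s here.", syn)
        )
      }
      planted[[length(planted) + 1L]] <<- tibble(
        doc_id = d, section = section, term_id = row$term_id,
        synonym = syn, specificity = spec
      )
    }
  }
  for (sec in c("title", "abstract", "mesh", "body")) {
    plant("specific", sec, cfg$specific_rates[[sec]])
    plant("relevant", sec, cfg$relevant_rates[[sec]])
  }
  planted <- dplyr::bind_rows(planted)
  retained <- sort(unique(planted$doc_id[planted$specificity == "specific"]))
  if (length(retained) == 0L) {
    stopf("inconsistent config: no document receives a specific term, so no corpus can host events")
  }

  # --- gene pool, gold set, GO mapping ----------------------------------
  genes <- new_gene_pool(cfg)
  writeLines(as.character(genes$gold), paths$gold_genes)
  go_rows <- dplyr::bind_rows(lapply(genes$ids, function(id) {
    tibble(entrez_id = id,
           go_id = sprintf("GO:%07d", 6900L + sample.int(40L, sample(1:3, 1))))
  }))
  write.table(go_rows, paths$gene2go, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- focus event mentions placed in retained documents ----------------
  tpls <- make_chain_templates(cfg, genes, cfg$n_interactions,
                               cfg$n_single_events, cfg$focus_hit_rate, "CH")
  mentions <- list()
  chain_rows <- list()
  mutation_rows <- list()
  for (tpl in tpls) {
    n_m <- sample_mentions_count(cfg$mean_mentions)
    host_docs <- sample(retained, n_m, replace = TRUE)
    sig <- NULL
    for (j in seq_len(n_m)) {
      has_mut <- runif(1) < cfg$mutation_sentence_rate
      mut <- if (has_mut) {
        random_mutation(linkable = runif(1) < cfg$mutation_linkable_fraction)
      } else NULL
      built <- build_chain_mention(tpl, swap = (j %% 2L == 0L), mutation = mut)
      d <- host_docs[j]
      if (length(docs[[d]]$body) > 0L) {
        docs[[d]]$body <- c(docs[[d]]$body, built$text)
        section <- "body"
        paragraph_index <- length(docs[[d]]$body) - 1L
        sentence_index <- 0L
      } else {
        sentence_index <- length(docs[[d]]$abstract_sentences)
        docs[[d]]$abstract_sentences <- c(docs[[d]]$abstract_sentences,
                                          built$text)
        section <- "abstract"
        paragraph_index <- NA_integer_
      }
      conf <- if (tpl$label == "tp") {
        rbeta(1, cfg$true_confidence_shape[1], cfg$true_confidence_shape[2])
      } else {
        rbeta(1, cfg$false_confidence_shape[1], cfg$false_confidence_shape[2])
      }
      m <- event_chain_mention(
        doc_id = d, sentence_text = built$text, root = built$root,
        section = section, paragraph_index = paragraph_index,
        sentence_index = sentence_index, confidence = conf,
        negated = runif(1) < cfg$negation_rate,
        speculated = runif(1) < cfg$speculation_rate,
        anatomy_terms = built$anatomy
      )
      sig <- canonical_signature(m)
      mentions[[length(mentions) + 1L]] <- m
      if (has_mut) {
        mutation_rows[[length(mutation_rows) + 1L]] <- dplyr::mutate(
          built$mutation, doc_id = d,
          mention_index = length(mentions), chain_id = tpl$chain_id
        )
      }
    }
    chain_rows[[length(chain_rows) + 1L]] <- tibble(
      chain_id = tpl$chain_id, signature = sig,
      n_participants = length(tpl$genes), label = tpl$label,
      gold_hit = tpl$gold_hit, frequency = n_m,
      doc_count = length(unique(host_docs))
    )
  }
  chain_manifest <- dplyr::bind_rows(chain_rows)
  # templates are deduplicated at sampling time; a collision here is a bug
  if (anyDuplicated(chain_manifest$signature)) {
    stopf("internal error: duplicate chain template signatures")
  }
  mutation_manifest <- if (length(mutation_rows) > 0L) {
    dplyr::bind_rows(mutation_rows)
  } else {
    tibble(normalized = character(), start = integer(), end = integer(),
           linkable = logical(), protein = character(),
           protein_span_start = integer(), protein_span_end = integer(),
           doc_id = character(), mention_index = integer(),
           chain_id = character())
  }

  # --- background corpus (same machinery, no enrichment bias) -----------
  bg_tpls <- make_chain_templates(cfg, genes, cfg$n_background_chains,
                                  ceiling(cfg$n_background_chains / 3),
                                  cfg$background_hit_rate, "BG")
  bg_mentions <- list()
  for (tpl in bg_tpls) {
    n_m <- sample_mentions_count(cfg$mean_mentions)
    for (j in seq_len(n_m)) {
      built <- build_chain_mention(tpl, swap = (j %% 2L == 0L))
      bg_mentions[[length(bg_mentions) + 1L]] <- event_chain_mention(
        doc_id = sprintf("BGDOC%04d", sample.int(cfg$n_docs, 1)),
        sentence_text = built$text, root = built$root,
        section = "abstract", sentence_index = 0L,
        confidence = rbeta(1, cfg$false_confidence_shape[1],
                           cfg$false_confidence_shape[2]),
        anatomy_terms = built$anatomy
      )
    }
  }

  # --- write documents ---------------------------------------------------
  doc_objs <- lapply(docs, function(d) {
    document(
      doc_id = d$doc_id, title = d$title,
      abstract = paste(d$abstract_sentences, collapse = " "),
      mesh = d$mesh, body = d$body, source = d$source
    )
  })
  write_documents(doc_objs, paths$documents)
  write_event_mentions(mentions, paths$events)
  write_event_mentions(bg_mentions, paths$background_events)

  # --- curation labels ---------------------------------------------------
  grouped <- group_event_chains(mentions)
  two_part <- chain_manifest[chain_manifest$n_participants == 2L, ]
  lab <- dplyr::inner_join(
    two_part[, c("signature", "label")],
    grouped[, c("signature", "confidence", "doc_count")],
    by = "signature"
  )
  write.table(lab, paths$curation_labels, sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(
    config = unclass(cfg),
    planted_terms = planted,
    retained_docs = retained,
    chains = chain_manifest,
    mutations = mutation_manifest,
    background = list(
      n_mentions = length(bg_mentions),
      n_gold_hits = sum(mentions_hit_gene_set(bg_mentions, genes$gold))
    ),
    gold_genes = genes$gold
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", null = "null"),
             paths$manifest)
  invisible(list(paths = paths, manifest = manifest))
}

#' Verify a bundle against its ground-truth manifest
#'
#' Re-runs the pipeline stages on a generated bundle and compares what the
#' package recovers with what the generator planted: the retained document
#' set and per-term plantings (corpus stage), grouped chain signatures with
#' frequencies and document counts (grouping stage), and mutation links
#' (linker stage, where precision is guaranteed by construction and recall
#' measures how many planted sentences used a linkable pattern).
#'
#' @param bundle_dir Directory written by [generate_bundle()].
#' @return List with `report` (tibble: stage, metric, value) and `pass`
#'   (logical: everything construction guarantees was recovered exactly).
#' @export
manifest_check <- function(bundle_dir) {
  manifest <- jsonlite::fromJSON(file.path(bundle_dir, "manifest.json"),
                                 simplifyVector = TRUE)
  lex <- load_lexicon(file.path(bundle_dir, "lexicon.tsv"))
  docs <- read_documents(file.path(bundle_dir, "documents.jsonl"))
  corpus <- build_corpus(docs, lex)

  retained_obs <- sort(vapply(corpus$documents, function(d) d$doc_id, ""))
  retained_exp <- sort(manifest$retained_docs)
  corpus_ok <- identical(retained_obs, retained_exp)

  planted <- as_tibble(manifest$planted_terms)
  planted_counts <- planted |>
    dplyr::filter(.data$doc_id %in% retained_exp) |>
    dplyr::count(.data$doc_id, .data$section, .data$term_id, name = "expected")
  match_counts <- corpus$matches |>
    dplyr::count(.data$doc_id, .data$section, .data$term_id, name = "observed")
  cmp <- dplyr::full_join(planted_counts, match_counts,
                          by = c("doc_id", "section", "term_id"))
  cmp[is.na(cmp)] <- 0L
  term_recall <- if (sum(cmp$expected) > 0) {
    100 * sum(pmin(cmp$expected, cmp$observed)) / sum(cmp$expected)
  } else 100
  term_precision <- if (sum(cmp$observed) > 0) {
    100 * sum(pmin(cmp$expected, cmp$observed)) / sum(cmp$observed)
  } else 100

  mentions <- read_event_mentions(file.path(bundle_dir, "events.json"))
  groups <- group_event_chains(mentions)
  chains <- as_tibble(manifest$chains)
  gcmp <- dplyr::left_join(
    chains, groups[, c("signature", "frequency", "doc_count")],
    by = "signature", suffix = c("_exp", "_obs")
  )
  group_ok <- nrow(groups) == nrow(chains) &&
    !anyNA(gcmp$frequency_obs) &&
    all(gcmp$frequency_exp == gcmp$frequency_obs) &&
    all(gcmp$doc_count_exp == gcmp$doc_count_obs)

  muts <- as_tibble(manifest$mutations)
  if (nrow(muts) > 0L) {
    found_links <- 0L; correct_links <- 0L
    for (i in seq_len(nrow(muts))) {
      m <- mentions[[muts$mention_index[i]]]
      det <- find_mutations(m$sentence_text)
      parts <- collect_participants(m$root)
      res <- link_mutations(m$sentence_text, parts, det)
      found_links <- found_links + nrow(res$links)
      if (muts$linkable[i] && nrow(res$links) > 0L) {
        correct_links <- correct_links +
          sum(res$links$mutation == muts$normalized[i] &
                res$links$protein == muts$protein[i])
      }
    }
    n_linkable <- sum(muts$linkable)
    link_precision <- if (found_links > 0) 100 * correct_links / found_links else 100
    link_recall <- if (n_linkable > 0) 100 * correct_links / n_linkable else 100
  } else {
    link_precision <- 100; link_recall <- 100
  }

  report <- tibble(
    stage = c("corpus", "corpus", "corpus", "grouping", "mutation_link",
              "mutation_link"),
    metric = c("retained_docs_exact", "term_precision", "term_recall",
               "groups_exact", "precision", "recall"),
    value = c(as.numeric(corpus_ok) * 100, term_precision, term_recall,
              as.numeric(group_ok) * 100, link_precision, link_recall)
  )
  pass <- corpus_ok && group_ok &&
    term_precision == 100 && term_recall == 100 &&
    link_precision == 100 && link_recall == 100
  list(report = report, pass = pass)
}
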