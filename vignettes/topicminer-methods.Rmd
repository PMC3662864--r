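---
title: "Building topic-specific molecular-interaction catalogues: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building topic-specific molecular-interaction catalogues: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicminer)
```

## The problem

Research fields such as pain biology accumulate literature far faster than
any curator can read it, yet the molecular findings scattered across those
articles — which proteins interact, where, under what regulation — are
exactly what mechanistic research needs in structured form. `topicminer`
implements a semi-automated route to a topic-specific molecular-interaction
catalogue: a weighted term dictionary retrieves and ranks a topic corpus;
pre-extracted molecular events (the output of an upstream event-extraction
system, supplied as annotations) are deduplicated into unique interactions;
context (mutations, polarity, anatomy, GO terms, topic and disease
relevancy) is attached; and a set of statistics quantifies how trustworthy
the result is and which parts deserve manual curation first.

The package operates entirely downstream of event extraction: it consumes
sentence-level event annotations with participant normalizations and never
performs named-entity recognition of genes, species disambiguation, or
event extraction itself.

## Dictionary and document scoring

Dictionary terms carry a category (one of twelve labels by default,
configurable) and a specificity class. *Specific* terms — those synonymous
with the topic, such as a pain disorder or an analgesic drug — weigh
$t = 2$; *relevant* terms, associated but not diagnostic (an anatomical
region, a physiological process), weigh $t = 1$. Synonym matching is exact
and case-sensitive; a synonym claimed by two entries is rejected at load
time, because ambiguous terms inflate false-positive retrieval.

Matching is a deterministic dictionary scan: a candidate must be flanked by
non-alphanumeric characters or string edges (so `pain` never fires inside
`pains`), and overlaps resolve leftmost-longest, the convention of
dictionary-based NER tools. Retrieval uses specific terms only; scoring
then uses every match. Each mention scores $t_i \cdot p_i$, with position
weight $p$ = 2 in the title, 1 in the abstract or a MeSH descriptor, and
0.25 in body text, and the document score is

$$ S = \sum_{i=1}^{n} t_i \, p_i $$

over all mentions (repeats each count). Per-category and per-term scores
are the same sum restricted to the relevant mentions. The section weights
are configurable because body-heavy full-text articles otherwise outscore
abstract-only records merely by length; the defaults already damp body
mentions to an eighth of a title mention per unit weight.

An optional abbreviation rule registers a parenthetical immediately after a
match (`morphine (MOR)`) as a document-local synonym and rescans once. It
is off by default: it approximates the abbreviation handling of upstream
NER post-processing without reproducing it.

Two evaluation helpers mirror how such corpora are audited:
`stratified_sample()` draws up to *k* documents per score band (seeded,
without replacement), and `compare_mesh_groups()` runs a rank-sum
comparison of scores between documents carrying a topic MeSH descriptor as
a major versus a minor topic. The Z statistic always comes from the
tie-corrected normal approximation; the p-value switches to the exact
rank-sum distribution when both groups have at most 50 untied values, so
that small audits are exact while corpus-scale comparisons stay cheap.

## Phrase ranking for dictionary growth

`extract_candidates()` enumerates within-sentence token n-grams from corpus
text, and `rank_candidates()` orders them for manual review by stop-word
fraction (ascending), then frequency, length, and finally alphabetically;
phrases that are all stop words are dropped. The multi-key lexicographic
order is a deliberate choice: the ranking criteria (stop-word proportion
and size) do not prescribe a blended score, and a lexicographic order is
the simplest total, deterministic scheme satisfying them. This tool is a
review aid, not a termhood statistic; C-value/TF-IDF-style measures are out
of scope.

## Event chains and grouping

An event chain is a nested molecular event from one sentence: one to three
events of the nine GENIA types. Structural rules are enforced at
construction: only binding takes multiple themes, only the three regulation
types may nest an event as theme or carry a cause, and nesting is capped at
three events.

Grouping identical interactions across sentences and documents is keyed on
a canonical signature — a parenthesized prefix serialization of the event
tree. Participants are identified by Entrez Gene ID when normalized
(`G2354`) and by lowercased surface text (`u:abc`) otherwise, never by gene
symbol, so naming variation cannot split a group. Binding themes are
order-free: sorted numerically by Entrez ID when all participants are
normalized, case-insensitive alphabetically when none are, and
normalized-before-unnormalized in mixed bindings (the mixed rule is this
package's choice; nothing upstream dictates it). Cause and theme of
regulations stay asymmetric — an A-regulates-B chain never merges with
B-regulates-A.

Participants normalized to different species are **not** merged even when
they share a homologene group: grouping is by Entrez ID, and homologene
serves reporting only. Self-interactions stay in the output but are
flagged, since downstream curation excludes them.

A grouped chain records total mention frequency, distinct documents,
distinct molecule slots (1 = single event, 2 = molecular interaction,
more = multi), the maximum extractor confidence over members, and aggregate
polarity/speculation (`all_negative` only when every mention is negated,
`mixed` when reports conflict). Context tables count anatomy terms per
mention and event types per group in two flavours: non-redundant (a type
counts once per group) and total (a regulation of a regulation counts
twice).

## Mutation detection and linking

Point mutations are matched in event sentences in three forms — `A123T`,
`Ala123Thr`, and `Ala123 to Thr` — and normalized to one-letter `wNm`. The
bare one-letter form requires a two-digit position; single-digit positions
are overwhelmingly gene-name lookalikes (`H2A`, `T4`) in running text, and
the two richer forms still cover single-digit sites.

Linking a mutation to a protein mention in the same sentence uses a
priority-ranked pattern table shipped as data
(`extdata/mutation_patterns.tsv`), not code: protein–hyphen–mutation, then
mutation-of/in-protein, mutation-for-the-protein, an enumeration pattern
that distributes `mutations A, B and C for P` over the single trailing
protein, and a disabled-by-default nearest-protein-within-five-tokens
fallback. When several patterns could fire, the lowest priority number
wins; each mutation links to at most one protein; mutations no pattern can
attach are returned unlinked. The contract is precision-oriented: a link
exists only because a pattern fired, so on template-generated sentences
precision is 1 by construction and recall measures template coverage.
Cross-sentence links are out of scope by design — the method cannot see
antecedents outside the sentence.

## Term-to-event relevancy

Each (term match, event mention) pair in a document receives a 5–100 score.
The tier table is a reconstruction: the constraints honoured are the 5–100
range, the 75–100 same-sentence band, sensitivity to distance, the
above-50 aggregation cutoff, and specificity weighting; the specific values
live in `default_relevancy_tiers()` and are editable.

* Same sentence: $75 + \mathrm{round}\!\left(25\,(1 - d/\max(L-1,1))\right)$,
  where $d$ is the token distance between term and event trigger and $L$
  the sentence length in tokens.
* Same paragraph 60; term in title 55; in MeSH 50; in abstract 45.
* Body-to-body placements: an adjacent paragraph scores 30; farther ones
  decay as $\max(5,\, 25 - 5(g-1))$ with paragraph gap $g$.

Two cells of this table were genuinely open and are package decisions: a
paragraph gap of exactly 1 maps to the fixed "same section" tier rather
than the decay formula (keeping the decay strictly below it), and when the
term sits in the body but the event in the title/abstract, the decay
formula applies with $g$ = the term's paragraph index + 1. Order
sensitivity is expressed through the proximity term only; no explicit
precede/follow bonus is added, since any such bonus would be invented
detail.

The overall relevancy of a grouped chain averages over the documents $D$
mentioning it:

$$ R = \frac{1}{|D|} \sum_{d \in D} \sum_{t:\ s_{td} > 50} w_t \,
       \frac{s_{td} - 50}{50}, $$

where $s_{td}$ is the *maximum* link score of term $t$ in document $d$
(per-document max, not sum — mention frequency must not double-count) and
$w_t$ the specificity weight. Disease relevancy uses the same machinery
with $w_t = 1$. Scores land on a 0–2-ish scale banded low (0), medium
(>0, ≤1), high (>1). The $(s-50)/50$ rescaling is chosen so that one
specific term at perfect same-sentence evidence contributes 2 in its
document — consistent with that banding.

## Curation and enrichment statistics

`confusion_metrics()` works on whatever cells an evaluation design
provides; metrics with missing inputs or zero denominators are `NA`, never
0, and percentages are kept at full precision internally.
`cohens_kappa()` uses the two-category formulation with chance agreement
from the marginal label proportions of the two curation rounds.
`fisher_enrichment()` reports the sample odds ratio $ad/bc$ (conditional
MLE available as an option for small tables) with the standard two-sided
exact p — the sum of hypergeometric probabilities at most the observed
table's — computed exactly up to a table total of 50 000 and by a
Haldane-corrected log-OR normal approximation beyond, where p-values under
machine precision are displayed as `< 2.2e-16` rather than 0.
`precision_by_strata()` splits curated records by extractor confidence and
document count, the two covariates that matter for curation triage, and
`fit_triage_model()` fits the binomial GLM (logit link) of correctness on
confidence, reporting the confidence at which an interaction becomes more
likely true than false ($-\beta_0/\beta_1$). Single-label input and
complete separation are errors; a slope whose Wald 95% CI covers zero
yields an `NA` threshold with a warning instead of a meaningless crossing
point. `top_mentions_precision()` estimates how many of a group's top-k
mentions by confidence a curator will find correct.

## The synthetic corpus

`generate_bundle()` produces a complete input set — lexicons, sectioned
documents, focus and background event mentions, gold genes, a gene2go
table, curation labels — plus a manifest of every planted truth, all as a
pure function of its seed. Its defaults are the study conditions, chosen
once: true and false interactions draw mention confidences from Beta
distributions with means 0.3 and 0.1 (the separation reported between
curated true and false extractor output); the gold-gene enrichment factor
is 2 on the odds scale, matching the magnitude of enrichment a
topic-focused corpus shows over a random background; planting rates put a
specific term in roughly half the documents; negation (0.1), speculation
(0.05) and mutation-sentence (0.15) rates are at the low end typical of
extractor annotations. Planted counts are placed exactly, never
sampled-then-lost, so the manifest is a ground truth rather than an
expectation.

The generator is structurally realistic and linguistically trivial:
sentences are templates with exact recorded offsets, synonyms carry digits
so filler text can never collide with them, and binding mentions alternate
participant order to exercise canonicalization. Passing
`manifest_check()` therefore demonstrates that the pipeline recovers
planted structure perfectly — sections, offsets, grouping keys, pattern
links — and *not* that it would handle the morphology, anaphora, or
tokenization quirks of real biomedical prose. Default problem sizes (80
documents, ~40 unique chains, ~100 mentions per corpus) keep a full
generate–run–verify cycle under a few seconds; the parameter-recovery
checks use 60 interaction templates per corpus across 20 seeds for the
enrichment factor and 2 000 simulated records for the triage threshold,
sizes at which Monte-Carlo error is small relative to the tolerance being
asserted.

## Pipeline and interface

`run_pipeline()` wires the stages in dependency order with plain-file
intermediates (TSV/JSONL/JSON), stderr logging of per-stage counts, and
errors that name the failing stage. The `topicminer` script under `exec/`
exposes a subcommand per stage plus `run`; every subcommand is a thin
wrapper over the exported functions.

## Known limitations

* The matcher is exact and case-sensitive; spelling variants must be
  listed as synonyms.
* Mutation linking never crosses sentences, and the shipped pattern list
  covers the common constructions only; recall on real text is bounded by
  template coverage.
* The relevancy tier values are reconstructions constrained, not
  determined, by their published behaviour; `default_relevancy_tiers()`
  exists precisely so they can be recalibrated against observed curation
  precision.
* The overall relevancy normalizes by documents mentioning the group;
  corpora where a group's documents vary wildly in length will see some
  dilution the model does not correct for.
* Sentence splitting is a simple punctuation-plus-capital rule, pluggable
  but not abbreviation-aware.
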