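#' Confusion-matrix evaluation metrics (percent scale)
#'
#' Computes precision, recall, F score, accuracy and true-negative rate from
#' raw confusion counts. Evaluation designs frequently lack some cells (a
#' precision-only audit has no negatives); metrics whose inputs are missing
#' -- or whose denominator is zero -- are reported as `NA`, never as zero.
#' Values are kept at full precision; round only for presentation.
#'
#' @param tp,fp Non-negative counts.
#' @param tn,fn Non-negative counts, or `NA` where the design lacks them.
#' @return Named list: `precision`, `recall`, `f_score`, `accuracy`,
#'   `tn_rate`, all on the 0-100 percent scale.
#' @export
confusion_metrics <- function(tp, fp, tn = NA, fn = NA) {
  for (x in list(tp, fp)) if (!is_count(x)) stopf("tp and fp must be counts")
  for (x in list(tn, fn)) {
    if (!(length(x) == 1L && (is.na(x) || is_count(x)))) {
      stopf("tn and fn must be counts or NA")
    }
  }
  rate <- function(num, den) if (is.na(den) || den == 0) NA_real_ else 100 * num / den
  precision <- rate(tp, tp + fp)
  recall <- rate(tp, tp + fn)
  f_score <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  total <- tp + fp + tn + fn
  accuracy <- rate(tp + tn, total)
  tn_rate <- rate(tn, tn + fp)
  list(precision = precision, recall = recall, f_score = f_score,
       accuracy = accuracy, tn_rate = tn_rate)
}

#' Cohen's kappa for two curation rounds
#'
#' Two-category (true-positive / false-positive label) agreement between an
#' original curation round ("before") and a blind re-curation ("after").
#' Chance agreement `P(E)` comes from the marginal label proportions of the
#' two rounds; `K = (P(A) - P(E)) / (1 - P(E))`.
#'
#' @param before,after Two-element vectors `c(tp, fp)` of label counts in
#'   each round; both must sum to the same total.
#' @param agreed Number of items labelled identically in both rounds.
#' @return List with `p_a`, `p_e`, `kappa`.
#' @export
cohens_kappa <- function(before, after, agreed) {
  stopifnot(length(before) == 2L, length(after) == 2L)
  total <- sum(before)
  if (sum(after) != total) stopf("rounds must label the same number of items")
  if (!is_count(agreed) || agreed > total) {
    stopf("agreed must be a count no larger than the total")
  }
  p_a <- agreed / total
  p_e <- (after[1] / total) * (before[1] / total) +
         (after[2] / total) * (before[2] / total)
  if (p_e >= 1) stopf("chance agreement P(E) = 1: kappa undefined")
  list(p_a = p_a, p_e = unname(p_e), kappa = unname((p_a - p_e) / (1 - p_e)))
}

# Two-sided Fisher p by Woolf's log-odds-ratio normal approximation with a
# Haldane 0.5 correction; used for tables too large for exact enumeration.
fisher_p_approx <- function(a, b, c, d) {
  lor <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
  se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c + 0.5) + 1 / (d + 0.5))
  2 * pnorm(-abs(lor / se))
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Two-sided Fisher test of the table `rbind(c(a, b), c(c, d))`. The exact
#' p-value (sum of hypergeometric probabilities no larger than the observed
#' table's, the standard two-sided convention) is computed for tables with
#' totals up to `exact_limit`; beyond that a log-odds-ratio normal
#' approximation is used, and p-values below machine precision are flagged
#' via `p_display` (`"< 2.2e-16"`) rather than printed as 0.
#'
#' The reported odds ratio is the sample OR `(a d) / (b c)` (zero cells give
#' `0`/`Inf` symbolically); the small-sample conditional-MLE OR is available
#' as an option.
#'
#' @param a,b,c,d Non-negative counts: `a`,`b` = focus-corpus hits/misses,
#'   `c`,`d` = background hits/misses.
#' @param or_method `"sample"` (default) or `"cmle"` (conditional MLE, exact
#'   tables only).
#' @param exact_limit Largest table total for which the exact test is used.
#' @return List with `odds_ratio`, `p_value`, `p_display`, `method`.
#' @export
fisher_enrichment <- function(a, b, c, d, or_method = c("sample", "cmle"),
                              exact_limit = 5e4) {
  or_method <- match.arg(or_method)
  for (x in list(a, b, c, d)) if (!is_count(x)) stopf("counts must be non-negative integers")
  total <- a + b + c + d
  if (total == 0) stopf("empty table")
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (total <= exact_limit) {
    ft <- fisher.test(tab)
    p <- ft$p.value
    method <- "exact"
    or <- if (or_method == "cmle") unname(ft$estimate) else NULL
  } else {
    p <- fisher_p_approx(a, b, c, d)
    method <- "log-OR normal approximation"
    or <- NULL
    if (or_method == "cmle") {
      warn("conditional-MLE OR unavailable for approximate tables; using sample OR")
    }
  }
  if (is.null(or)) {
    or <- if (b == 0 || c == 0) {
      if (a == 0 || d == 0) NaN else Inf
    } else {
      (a / b) / (c / d)
    }
  }
  list(
    odds_ratio = or,
    p_value = p,
    p_display = if (p < .Machine$double.eps) "< 2.2e-16" else format(p, digits = 4),
    method = method
  )
}

mentions_hit_gene_set <- function(mentions, gene_set) {
  vapply(mentions, function(m) {
    parts <- collect_participants(m$root)
    ids <- unlist(lapply(parts, function(p) p$entrez_id))
    length(ids) > 0L && any(ids %in% gene_set)
  }, TRUE)
}

#' Gene-set enrichment table for two corpora of event chains
#'
#' Counts, per corpus, the mention-level event chains in which at least one
#' participant's Entrez id belongs to a gold gene set (e.g. genes previously
#' linked to the topic), and lays out the 2x2 table comparing the focus
#' corpus against a background corpus, ready for [fisher_enrichment()].
#'
#' @param mentions_focus,mentions_background Lists of `tm_mention` objects
#'   (mention-level chains, i.e. before grouping).
#' @param gene_set Integer vector of Entrez ids.
#' @return List with `table` (tibble: corpus, hits, misses, total,
#'   percent) and `counts` (`a`, `b`, `c`, `d` for the Fisher test).
#' @export
gene_set_table <- function(mentions_focus, mentions_background, gene_set) {
  gene_set <- as.integer(gene_set)
  hit_f <- sum(mentions_hit_gene_set(mentions_focus, gene_set))
  hit_b <- sum(mentions_hit_gene_set(mentions_background, gene_set))
  n_f <- length(mentions_focus)
  n_b <- length(mentions_background)
  tabl <- tibble(
    corpus = c("focus", "background"),
    hits = c(hit_f, hit_b),
    misses = c(n_f - hit_f, n_b - hit_b),
    total = c(n_f, n_b),
    percent = c(
      if (n_f > 0) 100 * hit_f / n_f else NA_real_,
      if (n_b > 0) 100 * hit_b / n_b else NA_real_
    )
  )
  list(table = tabl,
       counts = list(a = hit_f, b = n_f - hit_f, c = hit_b, d = n_b - hit_b))
}

#' Read curation labels from TSV
#'
#' @param path TSV with columns `signature`, `label` (`tp`/`fp`),
#'   `confidence`, `doc_count`.
#' @return A tibble of curation records.
#' @export
read_curation_labels <- function(path) {
  rec <- as_tibble(read.delim(path, stringsAsFactors = FALSE, quote = ""))
  stopifnot(all(c("signature", "label", "confidence", "doc_count") %in% names(rec)))
  if (!all(rec$label %in% c("tp", "fp"))) stopf("labels must be 'tp' or 'fp'")
  rec
}

#' Curation precision by confidence and document-count strata
#'
#' Precision (`tp / (tp + fp)`, percent) of curated grouped interactions,
#' overall and within four strata: extractor confidence above/below a
#' cutoff, and interactions mentioned in more than one document versus a
#' single document. High-confidence and multi-document interactions are the
#' natural curation priorities; the strata quantify by how much.
#'
#' @param records Tibble of curation records (`label`, `confidence`,
#'   `doc_count`).
#' @param confidence_cutoff Confidence threshold (default 0.5).
#' @return Named list of percent precisions: `overall`, `above_cutoff`,
#'   `below_cutoff`, `multi_doc`, `single_doc`; empty strata give `NA`.
#' @export
precision_by_strata <- function(records, confidence_cutoff = 0.5) {
  if (nrow(records) == 0L) stopf("records must be non-empty")
  if (!all(records$label %in% c("tp", "fp"))) stopf("labels must be 'tp' or 'fp'")
  prec <- function(sub) {
    if (nrow(sub) == 0L) return(NA_real_)
    100 * sum(sub$label == "tp") / nrow(sub)
  }
  list(
    overall = prec(records),
    above_cutoff = prec(records[records$confidence > confidence_cutoff, ]),
    below_cutoff = prec(records[records$confidence <= confidence_cutoff, ]),
    multi_doc = prec(records[records$doc_count > 1, ]),
    single_doc = prec(records[records$doc_count <= 1, ])
  )
}

#' Logistic triage model on extractor confidence
#'
#' Fits a binomial GLM with logit link of the curated label (true positive =
#' 1) on the extractor confidence score, by maximum likelihood. The decision
#' threshold is the confidence at which the predicted probability of being a
#' true positive crosses 0.5, i.e. `-intercept / slope`; interactions above
#' it are more likely true than false and are the ones worth curating first.
#'
#' Degenerate inputs are signalled rather than silently fit: single-label
#' data and complete separation are errors, and a slope whose Wald 95%
#' confidence interval covers zero yields an `NA` threshold with a warning
#' (confidence then carries no usable signal).
#'
#' @param records Tibble with `label` (`tp`/`fp`) and `confidence`.
#' @return List: `intercept`, `slope`, `threshold`, `probabilities`
#'   (fitted per-record probability of being a true positive), `model`.
#' @export
fit_triage_model <- function(records) {
  if (!all(c("label", "confidence") %in% names(records))) {
    stopf("records need 'label' and 'confidence' columns")
  }
  y <- records$label == "tp"
  if (all(y) || !any(y)) stopf("both labels must be present to fit a triage model")
  fit <- withCallingHandlers(
    glm(y ~ confidence, data = data.frame(y = y, confidence = records$confidence),
        family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stopf("complete separation: confidence perfectly splits the labels")
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- coef(fit)
  ci <- confint.default(fit)["confidence", ]
  threshold <- if (co[2] > 0 && !(ci[1] < 0 && ci[2] > 0)) {
    unname(-co[1] / co[2])
  } else {
    warn("slope not distinguishable from zero; triage threshold undefined")
    NA_real_
  }
  list(
    intercept = unname(co[1]), slope = unname(co[2]), threshold = threshold,
    probabilities = unname(fit$fitted.values), model = fit
  )
}

#' Mean number of correct mentions among a group's top-k by confidence
#'
#' For each grouped interaction with per-mention correctness labels, counts
#' how many of its `k` highest-confidence mentions are correct, and averages
#' over groups. This estimates how many individual mentions a curator must
#' read before confirming a grouped interaction. Groups with fewer than `k`
#' labelled mentions are excluded with a warning.
#'
#' @param mention_labels Tibble with columns `signature`, `confidence`,
#'   `correct` (logical), one row per labelled mention.
#' @param k Top-k size (default 5).
#' @return List: `mean_correct`, `per_group` (tibble `signature`,
#'   `n_correct`), `excluded` (signatures with fewer than `k` mentions).
#' @export
top_mentions_precision <- function(mention_labels, k = 5L) {
  stopifnot(all(c("signature", "confidence", "correct") %in% names(mention_labels)))
  if (!is_count(k) || k <= 0) stopf("k must be a positive integer")
  sizes <- table(mention_labels$signature)
  excluded <- names(sizes)[sizes < k]
  if (length(excluded) > 0L) {
    warn(sprintf("%d group(s) with fewer than %d labelled mentions excluded",
                 length(excluded), k))
  }
  keep <- mention_labels[!mention_labels$signature %in% excluded, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(list(mean_correct = NA_real_,
                per_group = tibble(signature = character(), n_correct = integer()),
                excluded = excluded))
  }
  per_group <- keep |>
    dplyr::group_by(.data$signature) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .by_group = TRUE) |>
    dplyr::summarise(n_correct = sum(head(.data$correct, k)), .groups = "drop")
  list(mean_correct = mean(per_group$n_correct), per_group = per_group,
       excluded = excluded)
}
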