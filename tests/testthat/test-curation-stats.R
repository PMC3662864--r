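test_that("confusion metrics handle full and partial evaluation designs", {
  # full design with all four cells
  m <- confusion_metrics(tp = 36, fp = 1, tn = 109, fn = 14)
  expect_equal(m$precision, 100 * 36 / 37)
  expect_equal(m$recall, 100 * 36 / 50)
  expect_equal(m$f_score, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$accuracy, 100 * 145 / 160)
  expect_equal(m$tn_rate, 100 * 109 / 110)
  # precision/recall-only design
  pr <- confusion_metrics(tp = 380, fp = 0, fn = 44)
  expect_equal(pr$precision, 100)
  expect_equal(pr$recall, 100 * 380 / 424)
  expect_true(is.na(pr$accuracy))
  # degenerate: no positives at all
  deg <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(deg$precision))
  expect_true(is.na(deg$recall))
  expect_equal(deg$tn_rate, 100)
  # F equals the harmonic mean identity wherever defined
  withr::with_seed(2, {
    for (i in 1:20) {
      tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
      mm <- confusion_metrics(tp, fp, fn = fn)
      expect_equal(mm$f_score,
                   2 * mm$precision * mm$recall / (mm$precision + mm$recall))
      expect_true(mm$precision >= 0 && mm$precision <= 100)
      expect_true(mm$recall >= 0 && mm$recall <= 100)
    }
  })
})

test_that("kappa follows the marginal-chance formula and its invariances", {
  k <- cohens_kappa(before = c(27, 23), after = c(22, 28), agreed = 45)
  expect_equal(k$p_a, 0.9)
  expect_equal(k$p_e, 0.4952)
  expect_equal(k$kappa, (0.9 - 0.4952) / (1 - 0.4952))
  # perfect agreement with balanced marginals
  perfect <- cohens_kappa(c(25, 25), c(25, 25), agreed = 50)
  expect_equal(perfect$kappa, 1)
  # swapping the tp/fp labels consistently leaves kappa unchanged
  swapped <- cohens_kappa(before = c(23, 27), after = c(28, 22), agreed = 45)
  expect_equal(swapped$kappa, k$kappa)
  # kappa is 1 iff agreement is total (given P(E) < 1)
  expect_lt(cohens_kappa(c(25, 25), c(25, 25), agreed = 49)$kappa, 1)
  expect_error(cohens_kappa(c(50, 0), c(50, 0), agreed = 50), "undefined")
  expect_error(cohens_kappa(c(10, 10), c(9, 10), agreed = 19), "same number")
})

test_that("fisher p-values equal brute-force hypergeometric enumeration", {
  ft <- fisher_enrichment(5, 1, 2, 7)
  expect_equal(ft$p_value, fisher_exact_enum_p(5, 1, 2, 7), tolerance = 1e-9)
  # symmetric table: OR 1, p 1
  sym <- fisher_enrichment(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  # sweep all tables with row margins up to 12 against the oracle
  for (m in c(5L, 9L, 12L)) {
    for (a in 0:m) {
      for (cc in 0:m) {
        got <- fisher_enrichment(a, m - a, cc, m - cc)
        want <- fisher_exact_enum_p(a, m - a, cc, m - cc)
        expect_equal(got$p_value, want, tolerance = 1e-8,
                     info = sprintf("table (%d,%d,%d,%d)", a, m - a, cc, m - cc))
      }
    }
  }
  # transpose invariance of the sample OR; row/column swaps keep p
  t1 <- fisher_enrichment(7, 3, 2, 8)
  t2 <- fisher_enrichment(7, 2, 3, 8)
  expect_equal(t1$odds_ratio, t2$odds_ratio)
  expect_equal(t1$p_value, fisher_enrichment(2, 8, 7, 3)$p_value)
  expect_equal(t1$p_value, fisher_enrichment(3, 7, 8, 2)$p_value)
  # zero cells report the odds ratio symbolically
  expect_equal(fisher_enrichment(5, 0, 2, 7)$odds_ratio, Inf)
  expect_equal(fisher_enrichment(0, 5, 2, 7)$odds_ratio, 0)
})

test_that("huge tables fall back to a guarded approximation", {
  big <- fisher_enrichment(71685, 1506969, 47998, 2196618)
  expect_equal(big$method, "log-OR normal approximation")
  expect_lt(big$p_value, 2.2e-16)
  expect_equal(big$p_display, "< 2.2e-16")
  expect_equal(big$odds_ratio, (71685 / 1506969) / (47998 / 2196618))
})

test_that("gene-set tables count chains touching the gold set per corpus", {
  gold <- c(101L, 105L)
  focus <- list(mk_binding_mention(101, 110), mk_binding_mention(120, 130),
                mk_regulation_mention(140, 105))
  background <- list(mk_binding_mention(120, 130), mk_binding_mention(150, 160),
                     mk_binding_mention(170, 180))
  gst <- gene_set_table(focus, background, gold)
  expect_equal(gst$counts$a, 2L)
  expect_equal(gst$counts$b, 1L)
  expect_equal(gst$counts$c, 0L)
  expect_equal(gst$table$percent[1], 100 * 2 / 3)
  # empty gold set: no hits anywhere
  none <- gene_set_table(focus, background, integer())
  expect_equal(none$counts$a, 0L)
  # 3 chains, 1 containing a set gene
  third <- gene_set_table(focus[1:3], list(), 101L)
  expect_equal(third$table$percent[1], 100 / 3)
})

test_that("precision strata partition curated records as reported", {
  rec <- tibble::tibble(
    signature = sprintf("S%03d", 1:10),
    label = c("tp", "tp", "fp", "fp", "fp", "tp", "fp", "tp", "fp", "fp"),
    confidence = c(0.9, 0.8, 0.6, 0.2, 0.1, 0.3, 0.4, 0.7, 0.05, 0.15),
    doc_count = c(3L, 2L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 4L)
  )
  st <- precision_by_strata(rec, confidence_cutoff = 0.5)
  expect_equal(st$overall, 40)
  expect_equal(st$above_cutoff, 100 * 3 / 4)
  expect_equal(st$below_cutoff, 100 * 1 / 6)
  expect_equal(st$multi_doc, 100 * 3 / 4)
  expect_equal(st$single_doc, 100 * 1 / 6)
  # empty stratum yields NA, not zero
  all_low <- precision_by_strata(rec[rec$confidence < 0.5, ], 0.99)
  expect_true(is.na(all_low$above_cutoff))
  expect_error(precision_by_strata(rec[0, ]), "non-empty")
})

test_that("triage model recovers a known logistic threshold", {
  # labels generated from logit(p) = -2 + 8x: p = 0.5 at x = 0.25
  withr::with_seed(123, {
    x <- runif(2000)
    y <- rbinom(2000, 1, plogis(-2 + 8 * x))
  })
  rec <- tibble::tibble(label = ifelse(y == 1, "tp", "fp"), confidence = x)
  fit <- fit_triage_model(rec)
  expect_lt(abs(fit$threshold - 0.25), 0.03)
  expect_equal(length(fit$probabilities), 2000L)
  expect_true(all(fit$probabilities >= 0 & fit$probabilities <= 1))
  # estimates tighten with sample size (consistency)
  rec_small <- rec[1:200, ]
  fit_small <- fit_triage_model(rec_small)
  expect_true(is.finite(fit_small$slope))
  # degenerate inputs are signalled
  expect_error(fit_triage_model(tibble::tibble(label = rep("tp", 10),
                                               confidence = runif(10))),
               "both labels")
  sep <- tibble::tibble(label = c(rep("fp", 10), rep("tp", 10)),
                        confidence = c(runif(10, 0, 0.4), runif(10, 0.6, 1)))
  expect_error(fit_triage_model(sep), "separation")
  # labels independent of confidence: threshold undefined, with a warning
  withr::with_seed(99, {
    noise <- tibble::tibble(label = sample(c("tp", "fp"), 400, replace = TRUE),
                            confidence = runif(400))
  })
  expect_warning(noise_fit <- fit_triage_model(noise), "threshold undefined")
  expect_true(is.na(noise_fit$threshold))
})

test_that("top-k mention audit averages correct mentions per group", {
  two <- tibble::tibble(
    signature = rep(c("A", "B"), each = 5),
    confidence = rep(seq(0.9, 0.5, by = -0.1), 2),
    correct = c(rep(TRUE, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  )
  res <- top_mentions_precision(two, k = 5)
  expect_equal(res$mean_correct, 4)
  # all incorrect
  none <- two
  none$correct <- FALSE
  expect_equal(top_mentions_precision(none, 5)$mean_correct, 0)
  # 88 groups holding 335 correct among their top-5 mentions
  withr::with_seed(8, {
    n_groups <- 88L
    correct_flags <- sample(c(rep(TRUE, 335), rep(FALSE, 88 * 5 - 335)))
    big <- tibble::tibble(
      signature = rep(sprintf("G%02d", seq_len(n_groups)), each = 5L),
      confidence = runif(88 * 5),
      correct = correct_flags
    )
  })
  expect_equal(top_mentions_precision(big, 5)$mean_correct, 335 / 88)
  # undersized groups are excluded with a warning
  short <- rbind(two, tibble::tibble(signature = "C", confidence = 0.5,
                                     correct = TRUE))
  expect_warning(res2 <- top_mentions_precision(short, 5), "excluded")
  expect_equal(res2$mean_correct, 4)
})
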