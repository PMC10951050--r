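test_that("AUROC handles separation, ties, and matches the pair oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2),
                     c("basal", "basal", "luminal", "luminal")), 1)
  expect_equal(auroc(c(0.5, 0.5), c("basal", "luminal")), 0.5)
  expect_error(auroc(c(1, 2), c("basal", "basal")), "both")
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- c("basal", "luminal", sample(c("basal", "luminal"), n - 2,
                                           replace = TRUE))
    scores <- round(runif(n), 2)            # rounded scores force ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("fold summaries use the Student-t multiplier", {
  f <- data.frame(fold = 1:3, auroc = c(0.8, 0.8, 0.8))
  s <- summarize_fold_metrics(f)
  expect_equal(s$mean, 0.8)
  expect_equal(s$ci_low, 0.8)
  expect_equal(s$ci_high, 0.8)
  f <- data.frame(fold = 1:3, auroc = c(0.7, 0.8, 0.9))
  s <- summarize_fold_metrics(f)
  hw <- qt(0.975, 2) * sd(c(0.7, 0.8, 0.9)) / sqrt(3)
  expect_equal(s$ci_high - s$mean, hw)
  expect_equal(hw, 4.30265 * 0.1 / sqrt(3), tolerance = 1e-5)
  f2 <- data.frame(fold = 1:2, acc = c(0, 1))
  s2 <- summarize_fold_metrics(f2)
  expect_equal(s2$ci_high - s2$mean, 12.7062 * sd(c(0, 1)) / sqrt(2),
               tolerance = 1e-5)
  expect_error(summarize_fold_metrics(f2[1, ]), "at least 2")
})

test_that("confidence intervals shrink as fold spread shrinks", {
  width <- sapply(c(0.2, 0.1, 0.01), function(s) {
    f <- data.frame(fold = 1:3, m = 0.8 + c(-s, 0, s))
    r <- summarize_fold_metrics(f)
    r$ci_high - r$ci_low
  })
  expect_true(all(diff(width) < 0))
})

test_that("concatenated confusion matrices reproduce published-style TPRs", {
  # 58 high-confidence luminal calls, 50 correct; 16 basal calls, 14 correct
  preds <- data.frame(
    slide_id = sprintf("W%02d", 1:74),
    truth = rep(c("luminal", "basal"), c(58, 16)),
    predicted = c(rep("luminal", 50), rep("basal", 8),
                  rep("basal", 14), rep("luminal", 2)))
  cm <- confusion_concat(preds)
  expect_equal(sum(cm$table), 74)
  expect_equal(unname(100 * cm$tpr["luminal"]), 86.2, tolerance = 0.05)
  expect_equal(unname(100 * cm$tpr["basal"]), 87.5, tolerance = 0.05)
  # duplicated slide = leakage across folds
  expect_error(confusion_concat(rbind(preds, preds[1, ])), "leakage")
  # empty class row yields NA rate
  lumonly <- preds[preds$truth == "luminal", ]
  expect_true(is.na(confusion_concat(lumonly)$tpr["basal"]))
})

test_that("Fisher's exact test enumerates the hypergeometric support", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)   # modal symmetric table
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2), "greater"), 5 / 6)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2), "less"), 5 / 6)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Fisher p-values match the log-factorial oracle and stats::fisher.test", {
  set.seed(23)
  for (i in 1:50) {
    m <- matrix(rpois(4, 4) + 1, 2)
    p <- fisher_exact_2x2(m)
    expect_equal(p, oracle_fisher_two_sided(m), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-6)
    expect_equal(fisher_exact_2x2(m, "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_gte(p + 1e-12, min(fisher_exact_2x2(m, "greater"),
                              fisher_exact_2x2(m, "less")))
  }
})

test_that("rank tests reproduce exact small-sample p-values", {
  rs <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                   kind = "rank_sum", alternative = "less")
  expect_equal(rs$statistic, 0)             # U statistic, total separation
  expect_equal(rs$p_value, 1 / 20)          # 1 of choose(6,3) orderings
  sr <- rank_tests(c(2, 1, 3, 0.5, 4), kind = "signed_rank_one_tailed")
  expect_equal(sr$p_value, 1 / 32)          # all 5 differences positive
  kw <- rank_tests(c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                   rep(c("a", "b", "c"), each = 3),
                   kind = "kruskal_wallis")
  expect_equal(unname(kw$statistic), 0)
  expect_error(rank_tests(1:4, c("a", "a", "a", "b")[1:3],
                          kind = "rank_sum"), "aligned")
})

test_that("macro averaging differs from binary when classes are skewed", {
  truth <- rep(c("luminal", "basal"), c(8, 2))
  pred <- c(rep("luminal", 7), "basal", "basal", "luminal")
  b <- classification_metrics(truth, pred)
  m <- classification_metrics(truth, pred, average = "macro")
  expect_equal(b$accuracy, m$accuracy)
  expect_false(isTRUE(all.equal(b$f1, m$f1)))
  expect_equal(b$recall, 0.5)               # basal positive class
})
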