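# Cross-validation protocol, AUC, confusion matrices, odds-ratio tables and
# the trend test.

test_that("LOCO returns one score per original case with embedded SMOTE", {
  tab <- gen_feature_table(26, 81, 4, 1, 1.5, seed = 21)
  sc <- loco_cv(tab, smote_spec = list(multiplier = 2), selector = "none",
                k = 15, seed = 21)
  expect_equal(nrow(sc), 107)
  expect_identical(sc$case_id, tab$case_id)
  folds <- attr(sc, "folds")
  # doubling the minority: folds hold 131 (positive held out) or 132 cases
  expect_true(all(folds$n_train %in% c(131L, 132L)))
  expect_equal(sort(unique(folds$n_train[sc$label == 1])), 131L)
  expect_equal(sort(unique(folds$n_train[sc$label == 0])), 132L)
  expect_true(all(sc$risk_score >= 0 & sc$risk_score <= 1))
})

test_that("synthetic input rows train but are never scored", {
  tab <- gen_feature_table(20, 40, 3, 1, 1, seed = 2)
  aug <- smote(tab, target_ratio = 1, seed = 5)
  sc <- loco_cv(aug, smote_spec = NULL, selector = "none", k = 10, seed = 1)
  expect_equal(nrow(sc), nrow(tab))
  expect_true(all(sc$case_id %in% tab$case_id))
})

test_that("leakage canaries: label feature leaks, exact-match self never does", {
  # a feature equal to the label is legitimately learnable from the training
  # fold: AUC 1
  tab <- gen_feature_table(25, 45, 3, 1, 0, seed = 3)
  tab$f_leak <- as.numeric(tab$label)
  sc <- loco_cv(tab, smote_spec = list(target_ratio = 1), selector = "cfs",
                k = 15, seed = 3)
  expect_equal(roc_auc(sc$risk_score, sc$label)$auc, 1)

  # pure-noise table: if the held-out case leaked into SMOTE, selection or
  # the reference set, its own zero-distance copy (capped weight 1e12) would
  # drive AUC towards 1; a clean protocol stays at chance
  noise <- gen_feature_table(60, 60, 4, 1, 0, seed = 4)
  sc0 <- loco_cv(noise, smote_spec = list(target_ratio = 1), selector = "cfs",
                 k = 15, seed = 4)
  expect_lt(abs(roc_auc(sc0$risk_score, sc0$label)$auc - 0.5), 0.15)
})

test_that("AUC matches hand counts, ties, and the trapezoid oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.85, 0.7), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "imagerisk_undefined_metric")

  withr::with_seed(17, {
    for (rep in 1:100) {
      n <- sample(10:40, 1)
      s <- runif(n)
      l <- rbinom(n, 1, 0.4)
      if (length(unique(l)) < 2) next
      expect_equal(roc_auc(s, l)$auc, oracle_auc_trapezoid(s, l),
                   tolerance = 1e-12)
    }
  })

  # Hanley-McNeil SE is positive and shrinks with n
  a1 <- roc_auc(c(rnorm(20), rnorm(20, 1)), rep(c(0, 1), each = 20))
  a2 <- roc_auc(c(rnorm(200), rnorm(200, 1)), rep(c(0, 1), each = 200))
  expect_gt(a1$se, a2$se)
})

test_that("confusion matrices use score >= T and reproduce printed metrics", {
  sc <- c(0.9, 0.5, 0.4, 0.2)
  lab <- c(1, 1, 0, 0)
  cm <- confusion_at_threshold(sc, lab, 0.5)   # 0.5 counts as positive
  expect_equal(tidy(cm), tibble::tibble(tp = 2, fp = 0, fn = 0, tn = 2))
  cm0 <- confusion_at_threshold(sc, lab, 0)
  expect_equal(cm0$tp + cm0$fp, 4)

  withr::with_seed(8, {
    s <- runif(200); l <- rbinom(200, 1, 0.3)
    cm2 <- confusion_at_threshold(s, l, 0.5)
    expect_equal(cm2$tp, sum(s >= 0.5 & l == 1))
    expect_equal(cm2$tn, sum(s < 0.5 & l == 0))
  })

  # metrics of a perfect matrix are all 100
  perfect <- matrix_metrics(confusion_matrix(10, 0, 0, 20))
  expect_true(all(perfect == 100))
  # zero denominators give NA, not zero
  und <- matrix_metrics(confusion_matrix(0, 0, 0, 5))
  expect_true(is.na(und$sensitivity))
  expect_true(is.na(und$ppv))
})

test_that("quantile bins split near-equally and respect monotone relabeling", {
  withr::with_seed(23, s <- runif(1045))
  b <- quantile_bins(s, 5)
  expect_equal(unname(table(b)), rep(209L, 5), ignore_attr = TRUE)
  expect_identical(quantile_bins(rank(s), 5), b)   # rank invariance
  expect_identical(quantile_bins(s^3, 5), b)       # monotone transform
  b10 <- quantile_bins(seq(0.1, 1, 0.1), 5)
  expect_equal(unname(table(b10)), rep(2L, 5), ignore_attr = TRUE)
  expect_error(quantile_bins(1:3, 5), class = "imagerisk_invalid")
})

test_that("odds ratios and Woolf intervals follow the 2x2 arithmetic", {
  bins <- rep(1:2, c(10, 10))
  labels <- c(rep(1, 5), rep(0, 5), rep(1, 8), rep(0, 2))
  or <- odds_ratio_table(bins, labels)
  expect_equal(or$odds_ratio[1], 1)
  expect_true(or$baseline[1])
  expect_equal(or$odds_ratio[2], (8 * 5) / (2 * 5))
  # identical class odds to baseline: OR exactly 1
  flat <- odds_ratio_table(rep(1:2, each = 10), rep(c(1, 0), 10))
  expect_equal(flat$odds_ratio[2], 1)
  # zero cell triggers the flagged Haldane-Anscombe correction
  z <- odds_ratio_table(rep(1:2, each = 6), c(1, 1, 1, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  expect_true(z$corrected[2])
  expect_true(is.finite(z$odds_ratio[2]))
})

test_that("the trend test flags monotone tables and not flat ones", {
  bins <- rep(1:5, each = 100)
  pos <- c(5, 20, 50, 80, 95)
  labels <- unlist(lapply(pos, function(p) rep(c(1, 0), c(p, 100 - p))))
  tt <- trend_test(bins, labels)
  expect_lt(tt$p_value, 1e-6)

  flat <- unlist(lapply(rep(40, 5), function(p) rep(c(1, 0), c(p, 100 - p))))
  t0 <- trend_test(bins, flat)
  expect_lt(t0$statistic, 1e-10)
  expect_error(trend_test(rep(1:2, 5), rep(0:1, 5)), class = "imagerisk_invalid")
  expect_error(trend_test(rep(1:5, 4), rep(1, 20)),
               class = "imagerisk_undefined_metric")
})

test_that("evaluate_scores bundles consistent summaries", {
  tab <- gen_feature_table(40, 80, 4, 1, 2, seed = 33)
  sc <- loco_cv(tab, smote_spec = list(target_ratio = 1), selector = "cfs",
                k = 15, seed = 33)
  ev <- evaluate_scores(sc)
  expect_s3_class(ev, "risk_evaluation")
  expect_equal(nrow(ev$scores), 120)
  expect_equal(sum(tidy(ev$confusion)), 120)
  gl <- glance(ev)
  expect_equal(gl$n, 120)
  expect_true(gl$auc > 0.5)
  td <- tidy(ev)
  expect_true(all(td$bin %in% 1:5))
  expect_output(print(ev), "AUC")
})
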