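# The distance-weighted KNN risk score, SMOTE, CFS and the classifier
# interface.

test_that("knn distance and weight follow the model equations", {
  expect_equal(knn_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(knn_distance(c(3, 4), c(0, 0)), 5)
  expect_equal(knn_distance(c(4, 3), c(0, 0)), 5)   # permutation symmetric
  expect_error(knn_distance(1:3, 1:2), class = "imagerisk_invalid")

  expect_equal(knn_weight(2), 0.25)
  expect_equal(knn_weight(1), 1)
  expect_equal(knn_weight(0), 1e12)                  # capped at 1/eps^2
  expect_true(is.finite(knn_weight(0)))
})

test_that("the risk score reproduces hand-computed neighbourhoods", {
  # two positives at d = 1 (w = 1 each), one negative at d = 0.5 (w = 4):
  # P = 2 / (2 + 4) = 1/3
  refs <- tibble::tibble(case_id = c("p1", "p2", "n1"),
                         f1 = c(1, -1, 0.5), label = c(1L, 1L, 0L))
  m <- knn_model(refs, k = 3, standardize = FALSE)
  expect_equal(knn_risk_score(matrix(0, 1, 1), m)$risk_score, 1 / 3,
               tolerance = 1e-12)

  # all-positive neighbourhood: P = 1 exactly
  refs_pos <- tibble::tibble(case_id = paste0("c", 1:6),
                             f1 = c(1, 2, 3, 4, 5, 50),
                             label = c(1L, 1L, 1L, 1L, 1L, 0L))
  m2 <- knn_model(refs_pos, k = 5, standardize = FALSE)
  expect_equal(knn_risk_score(matrix(3, 1, 1), m2)$risk_score, 1)

  # equal distances, 5 positive + 10 negative neighbours: P = 1/3
  refs_eq <- tibble::tibble(case_id = paste0("c", 1:15),
                            f1 = rep(c(1, -1), c(8, 7)),
                            f2 = rep(c(0, 0), c(8, 7)),
                            label = rep(c(1L, 0L), c(5, 10)))
  refs_eq$f1 <- cos(2 * pi * (1:15) / 15)
  refs_eq$f2 <- sin(2 * pi * (1:15) / 15)
  m3 <- knn_model(refs_eq, k = 15, standardize = FALSE)
  expect_equal(knn_risk_score(matrix(c(0, 0), 1, 2), m3)$risk_score, 5 / 15,
               tolerance = 1e-12)
})

test_that("risk scores are probabilities and flip under label exchange", {
  tab <- gen_feature_table(40, 60, 4, 1, 1, seed = 8)
  m <- knn_model(tab, k = 15)
  sc <- knn_risk_score(tab, m)$risk_score
  expect_true(all(sc >= 0 & sc <= 1))
  flipped <- dplyr::mutate(tab, label = 1L - label)
  m_f <- knn_model(flipped, k = 15)
  sc_f <- knn_risk_score(flipped, m_f)$risk_score
  expect_equal(sc_f, 1 - sc, tolerance = 1e-12)
  # scale invariance of the score in the weights: doubling all features with
  # standardization off multiplies every distance by 2 and leaves P unchanged
  m_raw <- knn_model(tab, k = 15, standardize = FALSE)
  doubled <- dplyr::mutate(tab, dplyr::across(dplyr::starts_with("f"), ~ 2 * .x))
  m_dbl <- knn_model(doubled, k = 15, standardize = FALSE)
  expect_equal(knn_risk_score(doubled, m_dbl)$risk_score,
               knn_risk_score(tab, m_raw)$risk_score, tolerance = 1e-9)
})

test_that("scoring a training case excludes itself from the neighbourhood", {
  tab <- gen_feature_table(20, 20, 3, 1, 2, seed = 4)
  m <- knn_model(tab, k = 15)
  with_self <- knn_risk_score(dplyr::mutate(tab, case_id = paste0("q_", case_id)), m)
  without_self <- knn_risk_score(tab, m)
  # with a distinct id the case matches itself at d = 0 and the capped weight
  # dominates, pushing the score to its own label; with self-exclusion not
  expect_equal(round(with_self$risk_score), tab$label)
  expect_false(isTRUE(all.equal(with_self$risk_score, without_self$risk_score)))
  expect_error(knn_model(tab[1:10, ], k = 15),
               class = "imagerisk_invalid_model")
})

test_that("SMOTE doubles the minority exactly and preserves originals", {
  tab <- gen_feature_table(26, 81, 5, 1, 1, seed = 6)
  out <- smote(tab, multiplier = 2, seed = 10)
  expect_equal(nrow(out), 133)
  expect_equal(sum(out$label == 1), 52)
  expect_equal(sum(out$label == 0), 81)
  expect_equal(sum(out$synthetic), 26)
  restored <- dplyr::filter(out, !synthetic)
  expect_identical(restored, tab)

  # balancing an already balanced table is a no-op
  bal <- gen_feature_table(30, 30, 3, 1, 1, seed = 2)
  expect_identical(smote(bal, target_ratio = 1, seed = 1), bal)

  one_pos <- gen_feature_table(2, 30, 3, 1, 1, seed = 2)[-1, ]
  expect_error(smote(one_pos, target_ratio = 1, seed = 1),
               class = "imagerisk_insufficient_minority")
})

test_that("synthetic cases lie on segments between real minority cases", {
  tab <- gen_feature_table(40, 200, 4, 1, 1, seed = 9)
  out <- smote(tab, target_ratio = 1, k_neighbors = 5, seed = 3)
  syn <- dplyr::filter(out, synthetic)
  minority <- as.matrix(dplyr::filter(tab, label == 1)[, paste0("f", 1:4)])
  expect_gt(nrow(syn), 100)
  for (i in seq_len(nrow(syn))) {
    v <- as.numeric(syn[i, paste0("f", 1:4)])
    # componentwise betweenness: v within the box spanned by some pair of
    # real minority points, checked against the closest segment
    ok <- FALSE
    for (a in seq_len(nrow(minority))) {
      x0 <- minority[a, ]
      dirs <- sweep(minority, 2, x0)
      rel <- v - x0
      # u consistent across coordinates for the generating pair
      for (b in seq_len(nrow(minority))[-a]) {
        dd <- minority[b, ] - x0
        u <- if (any(dd != 0)) rel[which.max(abs(dd))] / dd[which.max(abs(dd))] else 0
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(rel - u * dd)) < 1e-9) { ok <- TRUE; break }
      }
      if (ok) break
    }
    expect_true(ok)
  }
})

test_that("CFS matches exhaustive best-subset search and handles redundancy", {
  # single informative + noise: the informative feature is selected
  tab <- gen_feature_table(80, 80, 4, 1, 2, seed = 12)
  sel <- cfs_select(tab)
  expect_true("f1" %in% sel)
  expect_identical(sort(sel), sort(oracle_cfs_best_subset(tab)))

  # duplicated informative feature: redundancy penalty keeps exactly one
  tab2 <- tab
  tab2$f1_copy <- tab2$f1
  sel2 <- cfs_select(tab2)
  expect_equal(sum(c("f1", "f1_copy") %in% sel2), 1)

  # oracle equivalence on several random tables at p <= 6
  withr::with_seed(77, {
    for (rep in 1:4) {
      t3 <- gen_feature_table(60, 60, 6, sample(1:3, 1),
                              effect_size = runif(1, 0.5, 2),
                              correlation = runif(1, 0, 0.5),
                              seed = sample.int(1e6, 1))
      expect_identical(sort(cfs_select(t3)), sort(oracle_cfs_best_subset(t3)))
    }
  })

  # singleton merit reduces to the absolute class correlation
  expect_equal(cfs_merit(tab, "f1"),
               abs(cor(tab$f1, tab$label)))
  # constant feature: correlation defined as 0, never selected
  tab$f_const <- 1
  expect_false("f_const" %in% cfs_select(tab))
})

test_that("the classifier interface scores in [0,1] and is seed-deterministic", {
  tab <- gen_feature_table(40, 60, 4, 1, 2, seed = 5)
  for (kind in c("knn", "random_forest", "svm", "ann")) {
    sc <- train_classifier(tab, kind = kind, seed = 42)
    p <- predict(sc, tab)
    expect_true(all(p >= 0 & p <= 1))
  }
  rf1 <- predict(train_classifier(tab, "random_forest", seed = 42), tab)
  rf2 <- predict(train_classifier(tab, "random_forest", seed = 42), tab)
  expect_identical(rf1, rf2)
  # separable data: training-set AUC 1 for the knn scorer (self-excluded)
  sep <- gen_feature_table(30, 30, 2, 1, 8, seed = 3)
  p <- predict(train_classifier(sep, "knn", k = 5), sep)
  expect_equal(roc_auc(p, sep$label)$auc, 1)
  expect_error(train_classifier(tab, "boosted_stump"))
})

test_that("broom-style accessors describe a fitted knn model", {
  tab <- gen_feature_table(30, 50, 3, 1, 1, seed = 1)
  m <- knn_model(tab, k = 10)
  td <- tidy(m)
  expect_equal(td$feature, paste0("f", 1:3))
  expect_true(all(is.finite(td$center)))
  gl <- glance(m)
  expect_equal(gl$n_reference, 80)
  expect_equal(gl$k, 10)
})
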