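# Model evaluation: leave-one-case-out cross-validation with SMOTE and
# feature selection embedded per fold, ROC AUC, confusion matrices at a
# fixed operating threshold, quantile-subgroup odds-ratio tables and the
# Cochran-Armitage trend test.

#' Leave-one-case-out cross-validation with embedded SMOTE and selection
#'
#' For each original (non-synthetic) case: hold it out, oversample the
#' remaining cases with SMOTE, run feature selection on the augmented
#' training fold, train the classifier, and score the held-out case once.
#' SMOTE and selection never see the held-out case, and synthetic cases are
#' used in training folds only — they are never scored. Standardization for
#' the KNN scorer is likewise learned inside each fold.
#'
#' @param table Case table of original cases (at least 2 per class).
#' @param smote_spec `NULL` for no oversampling, or a list with either
#'   `multiplier` or `target_ratio` and optional `k_neighbors` (see
#'   [smote()]).
#' @param selector `"cfs"` or `"none"`.
#' @param classifier Classifier kind, see [train_classifier()].
#' @param k KNN neighbourhood size.
#' @param seed Integer seed governing all per-fold randomness.
#' @return Tibble with one row per original case: `case_id`, `label`,
#'   `risk_score`. The `"folds"` attribute logs, per fold, the training-set
#'   size, the number of synthetic cases and the selected features.
#' @export
loco_cv <- function(table, smote_spec = list(target_ratio = 1),
                    selector = c("cfs", "none"),
                    classifier = "knn", k = 15, seed = 1) {
  selector <- match.arg(selector)
  if (!"synthetic" %in% names(table)) table$synthetic <- FALSE
  feats <- feature_columns(table)
  x_all <- case_matrix(table, feats)
  y_all <- as.integer(table$label)
  syn_all <- as.logical(table$synthetic)
  eval_idx <- which(!syn_all)
  if (length(unique(y_all[eval_idx])) < 2L ||
      min(table(y_all[eval_idx])) < 2L) {
    stop_invalid("need at least 2 original cases per class")
  }
  k_neighbors <- smote_spec$k_neighbors %||% 5

  scores <- numeric(length(eval_idx))
  fold_n <- integer(length(eval_idx))
  fold_syn <- integer(length(eval_idx))
  fold_sel <- character(length(eval_idx))
  withr::with_seed(seed, {
    for (ii in seq_along(eval_idx)) {
      i <- eval_idx[ii]
      tr <- setdiff(seq_len(nrow(x_all)), i)
      x_tr <- x_all[tr, , drop = FALSE]
      y_tr <- y_all[tr]
      if (length(unique(y_tr)) < 2L) {
        stop_invalid(sprintf("fold for case %s has a single class",
                             table$case_id[i]))
      }
      if (!is.null(smote_spec)) {
        res <- smote_core(x_tr, y_tr,
                          multiplier = smote_spec$multiplier,
                          target_ratio = smote_spec$target_ratio,
                          k_neighbors = k_neighbors)
        x_tr <- rbind(x_tr, res$x)
        y_tr <- c(y_tr, res$y)
      }
      sel <- if (selector == "cfs") {
        s <- cfs_core(x_tr, y_tr)
        if (length(s) == 0L) seq_along(feats) else s
      } else {
        seq_along(feats)
      }
      fold_n[ii] <- nrow(x_tr)
      fold_syn[ii] <- nrow(x_tr) - length(tr)
      fold_sel[ii] <- paste(feats[sel], collapse = ",")
      xs <- x_tr[, sel, drop = FALSE]
      q <- x_all[i, sel]
      if (classifier == "knn") {
        ctr <- colMeans(xs)
        scl <- apply(xs, 2, sd)
        scl[scl == 0 | !is.finite(scl)] <- 1
        xz <- sweep(sweep(xs, 2, ctr), 2, scl, `/`)
        qz <- (q - ctr) / scl
        if (nrow(xz) < k) {
          stop_invalid(sprintf("fold for case %s has fewer than k = %d cases",
                               table$case_id[i], k))
        }
        d2 <- colSums((t(xz) - qz)^2)
        nn <- order(d2)[seq_len(k)]
        w <- knn_weight(sqrt(d2[nn]))
        scores[ii] <- sum(w[y_tr[nn] == 1L]) / sum(w)
      } else {
        fold_tab <- as_tibble(as.data.frame(xs))
        names(fold_tab) <- feats[sel]
        fold_tab$case_id <- sprintf("fold_%d", seq_len(nrow(xs)))
        fold_tab$label <- y_tr
        sc <- train_classifier(fold_tab, kind = classifier,
                               features = feats[sel], k = k,
                               seed = sample.int(2^30, 1))
        qtab <- as_tibble(as.data.frame(matrix(q, nrow = 1)))
        names(qtab) <- feats[sel]
        scores[ii] <- predict(sc, qtab)
      }
    }
  })
  out <- tibble(case_id = as.character(table$case_id[eval_idx]),
                label = y_all[eval_idx], risk_score = scores)
  attr(out, "folds") <- tibble(case_id = out$case_id, n_train = fold_n,
                               n_synthetic = fold_syn, selected = fold_sel)
  out
}

#' ROC area under the curve with standard error
#'
#' Mann-Whitney AUC (`U / (n_pos n_neg)`, ties counted one half) with the
#' Hanley-McNeil standard error.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = positive).
#' @return One-row tibble: `auc`, `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_invalid("AUC undefined with a single class",
                 class = "imagerisk_undefined_metric")
  }
  r <- rank(scores)
  a <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  tibble(auc = a, se = se, n_pos = n_pos, n_neg = n_neg)
}

#' Build a confusion matrix object
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("confusion counts must be nonnegative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("predicted +", "predicted -"),
                              c("actual +", "actual -")))
  print(m)
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Confusion matrix at an operating threshold
#'
#' Predicts positive when `score >= threshold` (a score exactly at the
#' threshold counts as positive).
#'
#' @param scores Numeric risk scores in `[0, 1]`.
#' @param labels Binary labels.
#' @param threshold Operating threshold, default 0.5.
#' @return A [confusion_matrix()].
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  confusion_matrix(tp = sum(pred == 1L & labels == 1L),
                   fp = sum(pred == 1L & labels == 0L),
                   fn = sum(pred == 0L & labels == 1L),
                   tn = sum(pred == 0L & labels == 0L))
}

#' Performance metrics of a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' overall accuracy, reported as percentages rounded to one decimal. A
#' metric with a zero denominator is `NA` (undefined), never 0.
#'
#' @param cm A [confusion_matrix()] (or a list with `tp`, `fp`, `fn`, `tn`).
#' @return One-row tibble of the five percentages.
#' @export
matrix_metrics <- function(cm) {
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  tibble(
    sensitivity = pct(cm$tp, cm$tp + cm$fn),
    specificity = pct(cm$tn, cm$tn + cm$fp),
    ppv = pct(cm$tp, cm$tp + cm$fp),
    npv = pct(cm$tn, cm$tn + cm$fn),
    accuracy = pct(cm$tp + cm$tn, total)
  )
}

#' Rank-based quantile subgroups
#'
#' Assigns each case to one of `k` score-ordered subgroups of near-equal
#' size (sizes differ by at most one; ties and bin boundaries resolved by
#' stable case order, so any monotone transform of the scores gives the
#' same bins).
#'
#' @param scores Numeric scores.
#' @param k Number of subgroups (default 5, i.e. quintiles).
#' @return Integer vector of bin indices 1 (lowest scores) .. `k`.
#' @export
quantile_bins <- function(scores, k = 5) {
  if (k < 2) stop_invalid("k must be >= 2")
  if (length(scores) < k) stop_invalid("need at least k scores")
  dplyr::ntile(scores, k)
}

#' Subgroup odds-ratio table
#'
#' Positive/negative counts per subgroup, the odds ratio of each subgroup
#' against the baseline subgroup, and Woolf (log-normal) confidence
#' intervals `exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell
#' of a comparison is zero the Haldane-Anscombe 0.5 correction is applied to
#' that comparison and flagged in the `corrected` column.
#'
#' @param bins Subgroup index per case (e.g. from [quantile_bins()]).
#' @param labels Binary labels.
#' @param baseline Baseline subgroup (default the lowest bin).
#' @param conf_level Confidence level for the Woolf interval.
#' @return Tibble with one row per subgroup: `subgroup`, `positives`,
#'   `negatives`, `odds_ratio`, `ci_low`, `ci_high`, `baseline`,
#'   `corrected`.
#' @export
odds_ratio_table <- function(bins, labels, baseline = NULL,
                             conf_level = 0.95) {
  labels <- as.integer(labels)
  groups <- sort(unique(bins))
  baseline <- baseline %||% groups[1]
  pos <- vapply(groups, function(g) sum(bins == g & labels == 1L), integer(1))
  neg <- vapply(groups, function(g) sum(bins == g & labels == 0L), integer(1))
  b <- which(groups == baseline)
  if (pos[b] == 0 || neg[b] == 0) {
    stop_invalid("baseline subgroup must contain both classes")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(seq_along(groups), function(g) {
    if (g == b) {
      return(tibble(subgroup = groups[g], positives = pos[g],
                    negatives = neg[g], odds_ratio = 1,
                    ci_low = NA_real_, ci_high = NA_real_,
                    baseline = TRUE, corrected = FALSE))
    }
    a_ <- pos[g]; b_ <- neg[g]; c_ <- pos[b]; d_ <- neg[b]
    corrected <- any(c(a_, b_, c_, d_) == 0)
    if (corrected) {
      a_ <- a_ + 0.5; b_ <- b_ + 0.5; c_ <- c_ + 0.5; d_ <- d_ + 0.5
    }
    or <- (a_ * d_) / (b_ * c_)
    se <- sqrt(1 / a_ + 1 / b_ + 1 / c_ + 1 / d_)
    tibble(subgroup = groups[g], positives = pos[g], negatives = neg[g],
           odds_ratio = or, ci_low = exp(log(or) - z * se),
           ci_high = exp(log(or) + z * se),
           baseline = FALSE, corrected = corrected)
  })
  bind_rows(rows)
}

#' Cochran-Armitage trend test across ordered subgroups
#'
#' Tests for a linear trend in the positive-case proportion across ordered
#' subgroups (integer scores 1..k), the classical chi-squared trend test;
#' two-sided p value.
#'
#' @param bins Ordered subgroup index per case (at least 3 groups).
#' @param labels Binary labels.
#' @return One-row tibble: `statistic` (chi-squared, 1 df), `p_value`.
#' @export
trend_test <- function(bins, labels) {
  labels <- as.integer(labels)
  groups <- sort(unique(bins))
  if (length(groups) < 3L) stop_invalid("need at least 3 ordered subgroups")
  pos <- vapply(groups, function(g) sum(bins == g & labels == 1L), integer(1))
  tot <- vapply(groups, function(g) sum(bins == g), numeric(1))
  if (sum(pos) == 0 || sum(pos) == sum(tot)) {
    stop_invalid("degenerate table: one class absent",
                 class = "imagerisk_undefined_metric")
  }
  tt <- suppressWarnings(prop.trend.test(pos, tot, score = seq_along(groups)))
  tibble(statistic = unname(tt$statistic), p_value = unname(tt$p.value))
}

#' Evaluate per-case risk scores
#'
#' Bundles the full evaluation of a score vector: AUC with standard error,
#' the confusion matrix and derived metrics at the operating threshold, the
#' quantile-subgroup odds-ratio table, and the trend test across subgroups.
#'
#' @param scores Tibble from [loco_cv()] (columns `case_id`, `label`,
#'   `risk_score`) or a numeric vector (then `labels` is required).
#' @param labels Binary labels when `scores` is a vector.
#' @param threshold Operating threshold for the confusion matrix.
#' @param bins Number of score subgroups for the odds-ratio table.
#' @return Object of class `risk_evaluation`.
#' @export
evaluate_scores <- function(scores, labels = NULL, threshold = 0.5, bins = 5) {
  if (is.data.frame(scores)) {
    tab <- tibble(case_id = as.character(scores$case_id),
                  label = as.integer(scores$label),
                  risk_score = scores$risk_score)
  } else {
    if (is.null(labels)) stop_invalid("labels required with a score vector")
    tab <- tibble(case_id = sprintf("case_%04d", seq_along(scores)),
                  label = as.integer(labels), risk_score = scores)
  }
  auc <- roc_auc(tab$risk_score, tab$label)
  cm <- confusion_at_threshold(tab$risk_score, tab$label, threshold)
  bin_idx <- quantile_bins(tab$risk_score, bins)
  # subgroup statistics can be undefined (e.g. a single-class baseline bin
  # under strong separation); keep the rest of the evaluation usable
  or_tab <- tryCatch(odds_ratio_table(bin_idx, tab$label),
                     imagerisk_error = function(e) NULL)
  trend <- tryCatch(trend_test(bin_idx, tab$label),
                    imagerisk_error = function(e) NULL)
  structure(
    list(scores = tab, auc = auc$auc, auc_se = auc$se,
         threshold = threshold,
         confusion = cm, metrics = matrix_metrics(cm),
         bins = bin_idx, or_table = or_tab, trend = trend),
    class = "risk_evaluation"
  )
}

#' @export
print.risk_evaluation <- function(x, ...) {
  cat(sprintf("Risk model evaluation: %d cases (%d positive)\n",
              nrow(x$scores), sum(x$scores$label)))
  cat(sprintf("AUC = %.3f +/- %.3f\n", x$auc, x$auc_se))
  cat(sprintf("Confusion matrix at T = %.2f:\n", x$threshold))
  print(x$confusion)
  print(as.data.frame(x$metrics), row.names = FALSE)
  if (!is.null(x$trend)) {
    cat(sprintf("Trend across %d score subgroups: chi2 = %.2f, p = %.3g\n",
                max(x$bins), x$trend$statistic, x$trend$p_value))
  }
  invisible(x)
}

#' @export
tidy.risk_evaluation <- function(x, ...) {
  out <- x$scores
  out$bin <- x$bins
  out
}

#' @export
glance.risk_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n = nrow(x$scores), n_pos = sum(x$scores$label),
           auc = x$auc, auc_se = x$auc_se, threshold = x$threshold),
    x$metrics,
    tibble(trend_p = if (is.null(x$trend)) NA_real_ else x$trend$p_value)
  )
}
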