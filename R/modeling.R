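# Case-based risk modeling: distance-weighted KNN risk score, SMOTE minority
# oversampling, and correlation-based feature selection (CFS).
#
# A case table is a tibble with a `case_id` column, numeric feature columns,
# a binary `label` (1 = positive) and a logical `synthetic` flag marking
# SMOTE-interpolated rows.

feature_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("label", "synthetic"))
}

case_matrix <- function(table, features = NULL) {
  features <- features %||% feature_columns(table)
  x <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(x)) stop_invalid("case table contains missing feature values")
  storage.mode(x) <- "double"
  x
}

#' Euclidean feature-space distance between two cases
#'
#' `d = sqrt(sum_r (f_r(query) - f_r(reference))^2)` over a shared feature
#' space. Standardization, when wanted, is applied by the caller (the KNN
#' model standardizes with parameters learned from its reference cases).
#'
#' @param query,reference Numeric vectors of equal length.
#' @return Nonnegative scalar distance.
#' @export
knn_distance <- function(query, reference) {
  if (length(query) != length(reference)) {
    stop_invalid("feature dimension mismatch")
  }
  sqrt(sum((query - reference)^2))
}

#' Inverse-square distance weight
#'
#' `w = 1 / d^2`, the neighbour weight of the KNN risk score. The weight is
#' singular at zero distance, so distances at or below `epsilon` are capped
#' at `1 / epsilon^2` (an exact or near-exact feature match dominates the
#' neighbourhood but stays finite).
#'
#' @param d Nonnegative distance(s).
#' @param epsilon Cap distance for (near-)exact matches.
#' @return Weight(s), in `(0, 1/epsilon^2]`.
#' @export
knn_weight <- function(d, epsilon = 1e-6) {
  if (any(d < 0)) stop_invalid("distances must be nonnegative")
  ifelse(d <= epsilon, 1 / epsilon^2, 1 / d^2)
}

#' Fit a distance-weighted KNN risk model
#'
#' Stores the reference case table together with per-feature z-score
#' standardization parameters (learned from the reference cases only).
#' Scoring a query selects its `k` nearest references by Euclidean distance
#' in standardized feature space and returns
#' `P = sum(w_pos) / (sum(w_pos) + sum(w_neg))` over the inverse-square
#' distance weights of the positive and negative neighbours — a risk score
#' in `[0, 1]`.
#'
#' @param reference Case table (tibble with `case_id`, numeric features,
#'   `label`).
#' @param k Neighbourhood size (`k = N + M`, positives plus negatives among
#'   the neighbours); default 15.
#' @param features Feature columns to use (default: all numeric non-label
#'   columns).
#' @param standardize Standardize features to reference z-scores first.
#' @param epsilon Zero-distance cap, see [knn_weight()].
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(reference, k = 15, features = NULL, standardize = TRUE,
                      epsilon = 1e-6) {
  features <- features %||% feature_columns(reference)
  x <- case_matrix(reference, features)
  if (nrow(x) < k) {
    stop_invalid(sprintf("need at least k = %d reference cases, got %d",
                         k, nrow(x)),
                 class = "imagerisk_invalid_model")
  }
  if (!all(reference$label %in% c(0L, 1L))) stop_invalid("labels must be 0/1")
  if (length(unique(reference$label)) < 2L) {
    stop_invalid("reference set must contain both classes",
                 class = "imagerisk_invalid_model")
  }
  center <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scale_ <- if (standardize) apply(x, 2, sd) else rep(1, ncol(x))
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, `/`)
  structure(
    list(x = xs, label = as.integer(reference$label),
         case_id = as.character(reference$case_id),
         features = features, center = center, scale = scale_,
         k = as.integer(k), epsilon = epsilon, standardize = standardize),
    class = "knn_model"
  )
}

# Scores one standardized query vector against the model's reference matrix.
# `exclude` is a logical vector over references (self-exclusion for LOCO).
knn_score_vector <- function(model, q, exclude = NULL) {
  x <- model$x
  lab <- model$label
  if (!is.null(exclude) && any(exclude)) {
    x <- x[!exclude, , drop = FALSE]
    lab <- lab[!exclude]
  }
  if (nrow(x) < model$k) {
    stop_invalid("fewer references than k after exclusion",
                 class = "imagerisk_invalid_model")
  }
  d2 <- colSums((t(x) - q)^2)
  nn <- order(d2)[seq_len(model$k)]          # ties: stable in stored case order
  w <- knn_weight(sqrt(d2[nn]), model$epsilon)
  sum(w[lab[nn] == 1L]) / sum(w)
}

#' Distance-weighted KNN risk score
#'
#' Scores query cases against a fitted [knn_model()]. A reference case with
#' the same `case_id` as a query is excluded from that query's neighbourhood
#' (leave-one-case-out semantics when scoring the model's own training
#' cases).
#'
#' @param query A case table (tibble), a numeric vector (one case), or a
#'   numeric matrix (cases in rows).
#' @param model A [knn_model()].
#' @return A tibble with `case_id` (when available) and `risk_score` in
#'   `[0, 1]`.
#' @export
knn_risk_score <- function(query, model) {
  if (is.numeric(query) && is.null(dim(query))) {
    query <- matrix(query, nrow = 1)
  }
  if (is.data.frame(query)) {
    ids <- if ("case_id" %in% names(query)) as.character(query$case_id)
           else rep(NA_character_, nrow(query))
    q <- case_matrix(query, model$features)
  } else {
    ids <- rep(NA_character_, nrow(query))
    q <- query
    if (ncol(q) != length(model$features)) {
      stop_invalid("feature dimension mismatch")
    }
  }
  qs <- sweep(sweep(q, 2, model$center), 2, model$scale, `/`)
  scores <- vapply(seq_len(nrow(qs)), function(i) {
    excl <- if (!is.na(ids[i])) model$case_id == ids[i] else NULL
    knn_score_vector(model, qs[i, ], excl)
  }, numeric(1))
  tibble(case_id = ids, risk_score = scores)
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  knn_risk_score(newdata, object)$risk_score
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf(
    "Distance-weighted KNN risk model: %d reference cases (%d positive), k = %d, %d features\n",
    length(x$label), sum(x$label), x$k, length(x$features)))
  invisible(x)
}

#' @export
tidy.knn_model <- function(x, ...) {
  tibble(feature = x$features, center = unname(x$center),
         scale = unname(x$scale))
}

#' @export
glance.knn_model <- function(x, ...) {
  tibble(n_reference = length(x$label), n_positive = sum(x$label),
         k = x$k, n_features = length(x$features),
         standardized = x$standardize)
}

# SMOTE core on matrices; uses the current RNG state.
smote_core <- function(x, y, multiplier = NULL, target_ratio = NULL,
                       k_neighbors = 5) {
  counts <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (counts["1"] <= counts["0"]) 1L else 0L
  n_min <- sum(y == minority)
  n_maj <- length(y) - n_min
  if (is.null(multiplier) && is.null(target_ratio)) target_ratio <- 1
  n_syn <- if (!is.null(multiplier)) {
    if (multiplier < 1) stop_invalid("multiplier must be >= 1")
    round((multiplier - 1) * n_min)
  } else {
    max(0L, round(target_ratio * n_maj) - n_min)
  }
  if (n_syn == 0L) {
    return(list(x = x[0, , drop = FALSE], y = integer(0)))
  }
  if (n_min < 2L) {
    stop_invalid("minority class needs at least 2 cases for SMOTE",
                 class = "imagerisk_insufficient_minority")
  }
  xm <- x[y == minority, , drop = FALSE]
  kk <- min(k_neighbors, n_min - 1L)
  d <- as.matrix(dist(xm))
  diag(d) <- Inf
  nn_idx <- apply(d, 1, function(r) order(r)[seq_len(kk)])
  nn_idx <- matrix(nn_idx, nrow = kk)
  # canonical allocation: every minority case generates an equal share of
  # synthetics; any remainder is spread over a random subset
  base <- rep(seq_len(n_min), n_syn %/% n_min)
  extra <- n_syn %% n_min
  if (extra > 0L) base <- c(base, sample.int(n_min, extra))
  pick <- nn_idx[cbind(sample.int(kk, n_syn, replace = TRUE), base)]
  u <- runif(n_syn)
  x_syn <- xm[base, , drop = FALSE] +
    u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  list(x = x_syn, y = rep(minority, n_syn))
}

#' SMOTE minority oversampling
#'
#' Balances a two-class case table by interpolated synthetic minority cases:
#' each synthetic case is `x + u (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` a randomly chosen one of `x`'s `k_neighbors` nearest minority
#' neighbours (Euclidean distance on the raw features). Original rows are
#' returned untouched, in their input order, followed by the synthetic rows
#' flagged `synthetic = TRUE`; dropping the flagged rows recovers the input
#' table exactly.
#'
#' @param table Case table tibble (`case_id`, features, `label`,
#'   optionally `synthetic`).
#' @param multiplier Multiply the minority class by this factor (e.g. 2
#'   doubles it). Mutually exclusive with `target_ratio`.
#' @param target_ratio Oversample the minority until
#'   `minority ~= target_ratio * majority` (default 1, i.e. a 1:1 balance)
#'   when `multiplier` is not given.
#' @param k_neighbors Minority neighbourhood size for interpolation.
#' @param seed Integer seed for the interpolation draws.
#' @return The augmented case table.
#' @export
smote <- function(table, multiplier = NULL, target_ratio = NULL,
                  k_neighbors = 5, seed = 1) {
  if (!"synthetic" %in% names(table)) table$synthetic <- FALSE
  feats <- feature_columns(table)
  x <- case_matrix(table, feats)
  y <- as.integer(table$label)
  res <- withr::with_seed(seed, {
    smote_core(x, y, multiplier, target_ratio, k_neighbors)
  })
  if (length(res$y) == 0L) return(table)
  syn <- as_tibble(as.data.frame(res$x))
  names(syn) <- feats
  syn$case_id <- sprintf("syn_%04d", seq_len(nrow(syn)))
  syn$label <- res$y
  syn$synthetic <- TRUE
  bind_rows(table, syn[, names(table)])
}

# Correlations for CFS: r_cf = |cor(feature, label)| (point-biserial),
# r_ff = |cor(feature_i, feature_j)|; NAs from constant features become 0.
cfs_correlations <- function(x, y) {
  rcf <- suppressWarnings(abs(as.numeric(cor(x, y))))
  rcf[!is.finite(rcf)] <- 0
  rff <- suppressWarnings(abs(cor(x)))
  rff[!is.finite(rff)] <- 0
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

cfs_merit_from_cor <- function(rcf, rff, subset) {
  k <- length(subset)
  if (k == 0L) return(0)
  rbar_cf <- mean(rcf[subset])
  rbar_ff <- if (k > 1) {
    s <- rff[subset, subset, drop = FALSE]
    mean(s[upper.tri(s)])
  } else 0
  k * rbar_cf / sqrt(k + k * (k - 1) * rbar_ff)
}

#' CFS merit of a feature subset
#'
#' `merit = k rbar_cf / sqrt(k + k (k - 1) rbar_ff)` where `rbar_cf` is the
#' mean absolute feature-class correlation of the subset and `rbar_ff` the
#' mean absolute pairwise feature-feature correlation; a singleton's merit
#' is its absolute class correlation.
#'
#' @param table Case table with a binary `label` column.
#' @param subset Character vector of feature names (or integer indices).
#' @return The merit (scalar).
#' @export
cfs_merit <- function(table, subset) {
  feats <- feature_columns(table)
  x <- case_matrix(table, feats)
  cc <- cfs_correlations(x, as.integer(table$label))
  idx <- if (is.character(subset)) match(subset, feats) else as.integer(subset)
  if (anyNA(idx)) stop_invalid("unknown feature in subset")
  cfs_merit_from_cor(cc$rcf, cc$rff, idx)
}

# Best-first forward search maximizing CFS merit; stops after `max_stale`
# consecutive non-improving expansions (Weka's convention). Deterministic:
# candidate features are tried in index order and only strict improvements
# replace the incumbent.
cfs_core <- function(x, y, max_stale = 5L) {
  cc <- cfs_correlations(x, y)
  p <- ncol(x)
  best_set <- integer(0)
  best_merit <- 0
  frontier <- list(list(set = integer(0), merit = 0))
  stale <- 0L
  visited <- new.env(hash = TRUE)
  while (length(frontier) > 0L && stale < max_stale) {
    merits <- vapply(frontier, `[[`, numeric(1), "merit")
    pick <- which.max(merits)
    node <- frontier[[pick]]
    frontier <- frontier[-pick]
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$set)) {
      cand <- sort(c(node$set, f))
      key <- paste(cand, collapse = ",")
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      m <- cfs_merit_from_cor(cc$rcf, cc$rff, cand)
      frontier[[length(frontier) + 1L]] <- list(set = cand, merit = m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- cand
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  best_set
}

#' Correlation-based feature selection (CFS)
#'
#' Best-first forward search over feature subsets maximizing the CFS merit
#' (see [cfs_merit()]): rewarding features correlated with the class and
#' penalizing redundancy between selected features. Constant features have
#' class correlation 0 and are never selected. The search is deterministic,
#' with ties broken by feature order.
#'
#' @param table Case table with binary `label`.
#' @param features Candidate feature columns (default all).
#' @param max_stale Best-first patience (consecutive non-improving
#'   expansions before stopping).
#' @return Character vector of selected feature names (table order).
#' @export
cfs_select <- function(table, features = NULL, max_stale = 5L) {
  feats <- features %||% feature_columns(table)
  if (length(feats) < 2L) stop_invalid("need at least 2 candidate features")
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) stop_invalid("both classes must be present")
  x <- case_matrix(table, feats)
  feats[cfs_core(x, y, max_stale)]
}

#' Train a pluggable risk classifier
#'
#' One interface over the classifier kinds used by the pipeline. `"knn"` is
#' the native distance-weighted KNN risk score; `"random_forest"`, `"svm"`
#' and `"ann"` delegate to \pkg{randomForest}, \pkg{e1071} and \pkg{nnet}
#' and report the positive-class probability. All scorers map a feature
#' vector to a risk score in `[0, 1]` via [predict()].
#'
#' @param table Training case table (both classes present).
#' @param kind One of `"knn"`, `"random_forest"`, `"svm"`, `"ann"`.
#' @param features Feature columns to train on (default all).
#' @param k Neighbourhood size for `"knn"`.
#' @param seed Integer seed for the stochastic learners.
#' @param ... Passed to the underlying learner.
#' @return An object of class `risk_scorer`.
#' @export
train_classifier <- function(table, kind = c("knn", "random_forest", "svm", "ann"),
                             features = NULL, k = 15, seed = 1, ...) {
  kind <- match.arg(kind)
  features <- features %||% feature_columns(table)
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) stop_invalid("both classes must be present")
  x <- case_matrix(table, features)
  fit <- withr::with_seed(seed, switch(kind,
    knn = knn_model(table, k = k, features = features),
    random_forest = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = 200, ...),
    svm = e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, ...),
    ann = nnet::nnet(x = x, y = y, size = 3, decay = 0.01, maxit = 200,
                     trace = FALSE, ...)
  ))
  structure(list(kind = kind, fit = fit, features = features),
            class = "risk_scorer")
}

#' @export
predict.risk_scorer <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) case_matrix(newdata, object$features)
       else matrix(newdata, ncol = length(object$features))
  switch(object$kind,
    knn = knn_risk_score(
      if (is.data.frame(newdata)) newdata else x, object$fit)$risk_score,
    random_forest = unname(predict(object$fit, x, type = "prob")[, "1"]),
    svm = {
      pr <- predict(object$fit, x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    ann = as.numeric(predict(object$fit, x))
  )
}
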