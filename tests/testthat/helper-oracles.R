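# Independent brute-force oracles used to cross-check the package's
# implementations on tiny inputs.

# GLCM by explicit pair enumeration: loop over every pixel/voxel, look up its
# neighbour at `off`, count level pairs, symmetrize, normalize, average over
# offsets. Independent of the package's vectorized construction.
oracle_glcm <- function(x, mask = NULL, levels = 32L, offsets = NULL) {
  dims <- dim(x)
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (is.null(offsets)) {
    offsets <- if (length(dims) == 2L) list(c(1L, 0L), c(0L, 1L)) else
      list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  }
  vals <- x[mask]
  lo <- min(vals); hi <- max(vals)
  q <- array(1L, dims)
  if (hi > lo) {
    q[mask] <- pmin(levels, 1L + as.integer(floor((vals - lo) / (hi - lo) * levels)))
  }
  coords <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
  mats <- list()
  for (off in offsets) {
    cm <- matrix(0, levels, levels)
    for (r in seq_len(nrow(coords))) {
      p <- coords[r, ]
      pn <- p + off
      if (any(pn < 1L) || any(pn > dims)) next
      pl <- rbind(p); pnl <- rbind(pn)
      if (!mask[pl] || !mask[pnl]) next
      cm[q[pl], q[pnl]] <- cm[q[pl], q[pnl]] + 1
    }
    cm <- cm + t(cm)
    if (sum(cm) > 0) mats[[length(mats) + 1L]] <- cm / sum(cm)
  }
  Reduce(`+`, mats) / length(mats)
}

oracle_glcm_stats <- function(p) {
  lv <- nrow(p)
  i <- matrix(seq_len(lv), lv, lv); j <- t(i)
  nz <- p > 0
  list(entropy = -sum(p[nz] * log2(p[nz])),
       uniformity = sum(p^2),
       autocorrelation = sum(i * j * p))
}

# Trapezoidal ROC integration on tie-free scores (oracle for the
# Mann-Whitney AUC).
oracle_auc_trapezoid <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exhaustive best-subset CFS merit maximization (oracle for the best-first
# search at small p).
oracle_cfs_best_subset <- function(table) {
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("label", "synthetic"))
  best <- character(0); best_m <- 0
  for (k in seq_along(feats)) {
    for (s in utils::combn(feats, k, simplify = FALSE)) {
      m <- cfs_merit(table, s)
      if (m > best_m + 1e-12) { best_m <- m; best <- s }
    }
  }
  best
}
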