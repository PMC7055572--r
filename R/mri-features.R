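# Global kinetic contrast-enhancement features from paired pre/post breast
# MRI volumes. Axis convention: rows run anterior -> posterior, columns
# left -> right, third axis through slices.

#' Segment the breast region of an MRI volume
#'
#' Removes the air background by an automatic (Otsu) or fixed intensity
#' threshold, then removes all tissue at or posterior to a straight per-slice
#' separation line standing in for the pectoral boundary. With
#' `separation = "fit"` the line is a least-squares fit, per slice, of the
#' anterior tissue edge in the lateral margins of the image (columns outside
#' the breasts, where the first tissue row is the chest wall itself); a
#' numeric `separation` fixes the cut at that row for all slices.
#'
#' @param volume Numeric 3D array.
#' @param air_threshold `"otsu"` or a numeric intensity cutoff; voxels above
#'   it are tissue.
#' @param separation `"fit"` or a fixed row index.
#' @param wall_tol Columns whose anterior tissue edge lies within `wall_tol`
#'   rows of the most posterior edge in the slice are treated as chest-wall
#'   columns for the fit.
#' @return Logical array, the breast mask.
#' @export
segment_breast_region <- function(volume, air_threshold = "otsu",
                                  separation = "fit", wall_tol = 0.5) {
  dims <- dim(volume)
  if (length(dims) != 3L) stop_invalid("volume must be a 3D array")
  thr <- if (identical(air_threshold, "otsu")) otsu_threshold(volume)
         else as.numeric(air_threshold)
  fg <- volume > thr
  if (!any(fg)) {
    stop_invalid("all-air volume", class = "imagerisk_empty_segmentation")
  }
  mask <- array(FALSE, dims)
  rows <- seq_len(dims[1])
  for (z in seq_len(dims[3])) {
    sl <- fg[, , z]
    if (!any(sl)) next
    if (identical(separation, "fit")) {
      first_row <- apply(sl, 2, function(col) {
        w <- which(col)
        if (length(w) == 0L) NA_real_ else min(w)
      })
      wall_edge <- max(first_row, na.rm = TRUE)
      use <- which(!is.na(first_row) & first_row >= wall_edge - wall_tol)
      if (length(use) >= 2L) {
        fit <- stats::lm.fit(cbind(1, use), first_row[use])
        cut_row <- cbind(1, seq_len(dims[2])) %*% fit$coefficients
      } else if (length(use) == 1L) {
        cut_row <- rep(first_row[use], dims[2])
      } else {
        cut_row <- rep(dims[1] + 1, dims[2])
      }
    } else {
      cut_row <- rep(as.numeric(separation), dims[2])
    }
    keep <- outer(rows, as.numeric(cut_row), function(r, cc) r < cc - 1e-6)
    mask[, , z] <- sl & keep
  }
  if (!any(mask)) {
    stop_invalid("separation removed all tissue",
                 class = "imagerisk_empty_segmentation")
  }
  mask
}

#' Contrast-enhancement map
#'
#' Subtraction map `post - pre` within the breast mask, optionally after an
#' exhaustive integer-translation alignment of the post volume (search over
#' `-max_shift..max_shift` per axis, maximizing the in-mask Pearson
#' correlation). Voxels outside the mask are `NA`. The chosen shift is stored
#' in the `"shift"` attribute.
#'
#' @param pre,post Numeric arrays of identical shape.
#' @param mask Logical array, nonempty.
#' @param max_shift Maximum absolute translation searched per axis (0 = no
#'   registration).
#' @return Numeric array (`NA` outside mask) with attribute `shift`.
#' @export
enhancement_map <- function(pre, post, mask, max_shift = 0L) {
  if (!identical(dim(pre), dim(post)) || !identical(dim(pre), dim(mask))) {
    stop_invalid("pre/post/mask geometry mismatch")
  }
  if (!any(mask)) {
    stop_invalid("empty mask", class = "imagerisk_empty_segmentation")
  }
  ndim <- length(dim(pre))
  best_shift <- rep(0L, ndim)
  if (max_shift > 0L) {
    grid <- do.call(expand.grid, rep(list(seq(-max_shift, max_shift)), ndim))
    best_cor <- -Inf
    for (g in seq_len(nrow(grid))) {
      sh <- as.integer(grid[g, ])
      shifted <- shift_array(post, sh)
      ok <- mask & !is.na(shifted)
      if (sum(ok) < 2L) next
      if (sd(shifted[ok]) == 0 || sd(pre[ok]) == 0) {
        # degenerate in-mask intensities: minimize the variance of the
        # difference image (offset-invariant, like correlation)
        cc <- -var(shifted[ok] - pre[ok])
      } else {
        cc <- cor(shifted[ok], pre[ok])
      }
      if (cc > best_cor + 1e-12) {
        best_cor <- cc
        best_shift <- sh
      }
    }
    post <- shift_array(post, best_shift)
  }
  map <- post - pre
  map[!mask] <- NA_real_
  attr(map, "shift") <- best_shift
  map
}

# Translate an array by integer offsets, NA-filling the exposed border.
shift_array <- function(x, shift) {
  dims <- dim(x)
  out <- array(NA_real_, dims)
  src <- dst <- vector("list", length(dims))
  for (ax in seq_along(dims)) {
    s <- shift[ax]
    src[[ax]] <- seq_len(dims[ax]) - s
    keep <- src[[ax]] >= 1L & src[[ax]] <= dims[ax]
    dst[[ax]] <- seq_len(dims[ax])[keep]
    src[[ax]] <- src[[ax]][keep]
  }
  out_idx <- as.matrix(do.call(expand.grid, dst))
  src_idx <- as.matrix(do.call(expand.grid, src))
  out[out_idx] <- x[src_idx]
  out
}

kinetic_stat_names <- c("mean", "sd", "skewness", "top1_mean", "top5_mean")

kinetic_side_stats <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  sorted <- sort(v, decreasing = TRUE)
  c(mean = mean(v),
    sd = if (n > 1) sd(v) else 0,
    skewness = moment_skewness(v),
    top1_mean = mean(sorted[seq_len(ceiling(0.01 * n))]),
    top5_mean = mean(sorted[seq_len(ceiling(0.05 * n))]))
}

#' Global kinetic enhancement features
#'
#' Per-breast statistics of the enhancement map — mean, SD, skewness
#' (population moments, 0 for constant input), and the mean of the top 1%
#' and top 5% of sorted enhancement values (top-k count = `ceiling(k% * N)`,
#' never empty) — plus the bilateral absolute differences of each statistic.
#'
#' @param map Numeric array (enhancement map; `NA` allowed outside masks).
#' @param mask_left,mask_right Logical arrays, nonempty and disjoint.
#' @return One-row tibble with `left_*`, `right_*` and `delta_*` columns for
#'   each of the five statistics.
#' @export
kinetic_features <- function(map, mask_left, mask_right) {
  if (!any(mask_left)) {
    stop_invalid("empty left breast mask", class = "imagerisk_empty_segmentation")
  }
  if (!any(mask_right)) {
    stop_invalid("empty right breast mask", class = "imagerisk_empty_segmentation")
  }
  if (any(mask_left & mask_right)) {
    stop_invalid("left/right masks overlap", class = "imagerisk_inconsistent_mask")
  }
  l <- kinetic_side_stats(map[mask_left])
  r <- kinetic_side_stats(map[mask_right])
  out <- c(setNames(l, paste0("left_", kinetic_stat_names)),
           setNames(r, paste0("right_", kinetic_stat_names)),
           setNames(abs(l - r), paste0("delta_", kinetic_stat_names)))
  as_tibble(as.list(out))
}

#' Full kinetic feature extraction for one pre/post pair
#'
#' Segments the breast region, splits it at the midline into left and right
#' breasts, forms the enhancement map and returns the kinetic feature row.
#'
#' @inheritParams enhancement_map
#' @param case_id Case identifier for the output row.
#' @param ... Passed to [segment_breast_region()].
#' @return One-row tibble: `case_id` plus [kinetic_features()] columns.
#' @export
extract_mri_features <- function(pre, post, case_id = "case", max_shift = 0L,
                                 ...) {
  mask <- segment_breast_region(pre, ...)
  dims <- dim(pre)
  mid <- dims[2] / 2
  cols <- outer(rep(1, dims[1]), seq_len(dims[2]))
  left_cols <- array(rep(cols <= mid, dims[3]), dims)
  map <- enhancement_map(pre, post, mask, max_shift = max_shift)
  feats <- kinetic_features(map, mask & left_cols, mask & !left_cols)
  dplyr::bind_cols(tibble(case_id = case_id), feats)
}
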