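# Lung-CT emphysema quantification and abdominal-CT adiposity features.
#
# Emphysema follows the standard density-mask convention: lung voxels at or
# below -950 HU. Fat uses the -140..40 HU window. Lung and body masks are
# inputs (from the phantom generators or the user); automatic organ
# segmentation is out of scope.

#' Emphysema density mask
#'
#' Lung voxels with attenuation at or below the threshold (default -950 HU,
#' inclusive), the standard CT emphysema surrogate.
#'
#' @param volume Numeric array in HU.
#' @param lung_mask Logical array of the same shape, nonempty.
#' @param threshold HU cutoff; voxels `<= threshold` are emphysema.
#' @return Logical array.
#' @export
emphysema_mask <- function(volume, lung_mask, threshold = -950) {
  if (!identical(dim(volume), dim(lung_mask))) {
    stop_invalid("volume/mask shape mismatch")
  }
  if (!any(lung_mask)) {
    stop_invalid("empty lung mask", class = "imagerisk_empty_segmentation")
  }
  lung_mask & volume <= threshold
}

#' Emphysema volume fraction
#'
#' Fraction of the lung occupied by the emphysema mask, volume-weighted by
#' voxel spacing (which cancels for isotropic masks but keeps the quantity a
#' true volume ratio).
#'
#' @param emph_mask,lung_mask Logical arrays; `emph_mask` must be a subset of
#'   `lung_mask`.
#' @param spacing Voxel spacing per axis in mm.
#' @return Fraction in `[0, 1]`.
#' @export
emphysema_percentage <- function(emph_mask, lung_mask,
                                 spacing = rep(1, length(dim(lung_mask)))) {
  if (any(emph_mask & !lung_mask)) {
    stop_invalid("emphysema mask not contained in lung mask",
                 class = "imagerisk_inconsistent_mask")
  }
  if (!any(lung_mask)) {
    stop_invalid("empty lung mask", class = "imagerisk_empty_segmentation")
  }
  vox <- prod(spacing)
  (sum(emph_mask) * vox) / (sum(lung_mask) * vox)
}

default_offsets <- function(ndim) {
  if (ndim == 2L) list(c(1L, 0L), c(0L, 1L)) else
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
}

#' Gray-level co-occurrence (GLCM) texture features
#'
#' Quantizes the in-region intensities to `levels` equal-width bins over the
#' region's own range (so the features are invariant to affine intensity
#' rescaling), accumulates a co-occurrence matrix of level pairs at each
#' spatial offset, symmetrizes and normalizes it to sum 1, and averages the
#' normalized matrices over offsets. Features use 1-based level indices
#' `i, j`:
#' entropy `-sum p log2 p` (bits), uniformity (energy) `sum p^2`,
#' autocorrelation `sum i j p`, plus contrast, dissimilarity, homogeneity,
#' correlation, maximum probability, cluster shade and cluster prominence.
#'
#' A constant region maps to the single cell `(1, 1)`: entropy 0,
#' uniformity 1, autocorrelation 1.
#'
#' @param x Numeric 2D/3D array.
#' @param mask Optional logical array restricting the region (default: all).
#' @param levels Number of gray levels `>= 2`.
#' @param offsets List of integer displacement vectors (default: one-voxel
#'   steps along each axis).
#' @return One-row tibble of the ten texture features, prefixed `glcm_`.
#' @export
glcm_features <- function(x, mask = NULL, levels = 32L, offsets = NULL) {
  if (levels < 2) stop_invalid("levels must be >= 2")
  dims <- dim(x)
  if (is.null(dims)) stop_invalid("x must be a 2D or 3D array")
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) stop_invalid("x/mask shape mismatch")
  if (!any(mask)) {
    stop_invalid("empty region", class = "imagerisk_empty_segmentation")
  }
  if (is.null(offsets)) offsets <- default_offsets(length(dims))

  vals <- x[mask]
  lo <- min(vals)
  hi <- max(vals)
  q <- array(1L, dims)
  if (hi > lo) {
    q[mask] <- pmin(levels, 1L + as.integer(floor((vals - lo) / (hi - lo) * levels)))
  }

  pmats <- lapply(offsets, function(off) {
    cooccurrence_matrix(q, mask, off, levels)
  })
  pmats <- pmats[!vapply(pmats, is.null, logical(1))]
  if (length(pmats) == 0) {
    stop_invalid("no co-occurring pairs for the given offsets")
  }
  p <- Reduce(`+`, pmats) / length(pmats)

  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p))
  sd_j <- sqrt(sum((j - mu_j)^2 * p))
  nz <- p > 0
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else 0

  tibble(
    glcm_entropy = -sum(p[nz] * log2(p[nz])),
    glcm_uniformity = sum(p^2),
    glcm_autocorrelation = sum(i * j * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_homogeneity = sum(p / (1 + abs(i - j))),
    glcm_correlation = corr,
    glcm_max_probability = max(p),
    glcm_cluster_shade = sum((i + j - mu_i - mu_j)^3 * p),
    glcm_cluster_prominence = sum((i + j - mu_i - mu_j)^4 * p)
  )
}

# Symmetric normalized co-occurrence matrix of quantized array `q` at one
# integer offset, restricted to pairs with both ends in `mask`.
cooccurrence_matrix <- function(q, mask, off, levels) {
  dims <- dim(q)
  ndim <- length(dims)
  if (length(off) != ndim) stop_invalid("offset dimensionality mismatch")
  src <- lapply(seq_len(ndim), function(ax) {
    r <- seq_len(dims[ax])
    r[r + off[ax] >= 1L & r + off[ax] <= dims[ax]]
  })
  if (any(vapply(src, length, integer(1)) == 0L)) return(NULL)
  dst <- lapply(seq_len(ndim), function(ax) src[[ax]] + off[ax])
  qa <- do.call(`[`, c(list(q), src, list(drop = FALSE)))
  qb <- do.call(`[`, c(list(q), dst, list(drop = FALSE)))
  ma <- do.call(`[`, c(list(mask), src, list(drop = FALSE)))
  mb <- do.call(`[`, c(list(mask), dst, list(drop = FALSE)))
  ok <- ma & mb
  if (!any(ok)) return(NULL)
  counts <- matrix(0, levels, levels)
  tab <- table(factor(qa[ok], levels = seq_len(levels)),
               factor(qb[ok], levels = seq_len(levels)))
  counts <- counts + as.matrix(tab)
  counts <- counts + t(counts)
  counts / sum(counts)
}

#' Emphysema feature panel (21 features)
#'
#' A fixed-schema global emphysema description of a lung CT volume in three
#' subgroups: volume/shape (emphysema percentage, blob count, mean and
#' maximum blob volume, sphericity of the largest blob), lung density
#' distribution (HU mean, SD, skewness, kurtosis, 5th and 15th percentiles),
#' and GLCM texture of the binary emphysema-pattern map (ten features, see
#' [glcm_features()]). Blob labelling uses 26-connectivity; sphericity is
#' `pi^(1/3) (6V)^(2/3) / A` with the surface area `A` estimated from exposed
#' voxel faces with a stereological staircase correction. With no emphysema
#' the blob statistics are 0 and the texture block describes the (constant)
#' empty pattern map.
#'
#' @param volume Numeric array in HU.
#' @param lung_mask Logical array, nonempty.
#' @param threshold Density-mask cutoff in HU.
#' @param spacing Voxel spacing in mm per axis.
#' @param levels Gray levels for the texture block.
#' @return One-row tibble with 21 named feature columns (schema is fixed
#'   across inputs).
#' @export
emphysema_feature_panel <- function(volume, lung_mask, threshold = -950,
                                    spacing = rep(1, length(dim(volume))),
                                    levels = 32L) {
  emph <- emphysema_mask(volume, lung_mask, threshold)
  vox <- prod(spacing)
  pct <- emphysema_percentage(emph, lung_mask, spacing)

  lab <- label_components(emph)
  n_blobs <- max(lab)
  if (n_blobs > 0) {
    sizes <- tabulate(lab[lab > 0L]) * vox
    largest <- which.max(sizes)
    sph <- blob_sphericity(lab == largest, spacing)
    mean_vol <- mean(sizes)
    max_vol <- max(sizes)
  } else {
    mean_vol <- 0
    max_vol <- 0
    sph <- 0
  }

  hu <- volume[lung_mask]
  density <- tibble(
    hu_mean = mean(hu),
    hu_sd = sd(hu),
    hu_skewness = moment_skewness(hu),
    hu_kurtosis = moment_kurtosis(hu),
    hu_p05 = quantile(hu, 0.05, names = FALSE),
    hu_p15 = quantile(hu, 0.15, names = FALSE)
  )

  pattern <- array(0, dim(volume))
  pattern[emph] <- 1
  texture <- glcm_features(pattern, lung_mask, levels = levels)

  dplyr::bind_cols(
    tibble(emphysema_percentage = pct, blob_count = as.integer(n_blobs),
           mean_blob_volume = mean_vol, max_blob_volume = max_vol,
           largest_blob_sphericity = sph),
    density, texture
  )
}

# Sphericity of a single blob mask: pi^(1/3) * (6V)^(2/3) / A. The surface
# area counts exposed voxel faces and divides by 3/2, the stereological
# correction for the staircase overcount (a surface patch with unit normal n
# exposes |n_x| + |n_y| + |n_z| face area per true area; its average over a
# sphere is 3/2), so a voxelized sphere reports sphericity near 1.
blob_sphericity <- function(blob, spacing) {
  dims <- dim(blob)
  ndim <- length(dims)
  vox <- prod(spacing)
  V <- sum(blob) * vox
  A <- 0
  for (ax in seq_len(ndim)) {
    face <- vox / spacing[ax]
    for (dlt in c(-1L, 1L)) {
      idx <- which(blob)
      coords <- arrayInd(idx, dims)
      nb <- coords
      nb[, ax] <- nb[, ax] + dlt
      off <- nb[, ax] < 1L | nb[, ax] > dims[ax]
      lin <- rep(1L, length(idx))
      inb <- !off
      if (any(inb)) {
        lin[inb] <- nb[inb, 1] + (nb[inb, 2] - 1L) * dims[1] +
          (if (ndim == 3L) (nb[inb, 3] - 1L) * dims[1] * dims[2] else 0L)
      }
      exposed <- off | (inb & !blob[ifelse(inb, lin, 1L)])
      A <- A + sum(exposed) * face
    }
  }
  A <- A / 1.5
  if (A <= 0) return(0)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Fat mask from an HU window
#'
#' Body voxels inside the fat attenuation window (default -140..40 HU, both
#' ends inclusive).
#'
#' @param volume Numeric array in HU.
#' @param body_mask Logical array, nonempty.
#' @param range Length-2 HU window `c(low, high)`.
#' @return Logical array.
#' @export
fat_mask <- function(volume, body_mask, range = c(-140, 40)) {
  if (!identical(dim(volume), dim(body_mask))) {
    stop_invalid("volume/mask shape mismatch")
  }
  if (!any(body_mask)) {
    stop_invalid("empty body mask", class = "imagerisk_empty_segmentation")
  }
  body_mask & volume >= range[1] & volume <= range[2]
}

#' Split fat into subcutaneous and visceral compartments
#'
#' Subcutaneous fat (SFA) is the union of fat connected components that touch
#' the boundary shell of the body (the body mask minus its erosion by
#' `shell_mm`); visceral fat (VFA) is all remaining fat. The two masks
#' partition the fat mask exactly.
#'
#' @param fat_mask,body_mask Logical arrays; `fat_mask` must be a subset of
#'   `body_mask`.
#' @param spacing Pixel/voxel spacing in mm per axis.
#' @param shell_mm Depth of the boundary shell in mm.
#' @return List with logical `sfa_mask` and `vfa_mask`.
#' @export
split_sfa_vfa <- function(fat_mask, body_mask,
                          spacing = rep(1, length(dim(body_mask))),
                          shell_mm = 10) {
  if (any(fat_mask & !body_mask)) {
    stop_invalid("fat mask not contained in body mask",
                 class = "imagerisk_inconsistent_mask")
  }
  shell <- body_mask & boundary_distance(body_mask, spacing) <= shell_mm
  lab <- label_components(fat_mask)
  touching <- unique(lab[shell & lab > 0L])
  sfa <- array(lab %in% touching & lab > 0L, dim(fat_mask))
  list(sfa_mask = sfa & fat_mask, vfa_mask = fat_mask & !sfa)
}

#' Adiposity feature set
#'
#' Areas/volumes (voxel count times voxel size), VFA/SFA ratio, and HU
#' mean/SD per fat compartment; when a total-psoas-area (TPA) mask is
#' supplied, its size and HU heterogeneity (SD) are appended. Without a TPA
#' mask those columns are absent, not zero. The VFA/SFA ratio is 0 when VFA
#' is empty and `NA` when SFA is empty.
#'
#' @param sfa_mask,vfa_mask Logical arrays from [split_sfa_vfa()].
#' @param volume Numeric array in HU.
#' @param spacing Spacing in mm per axis.
#' @param tpa_mask Optional logical array for the psoas compartment.
#' @return One-row tibble of adiposity features (areas in mm^2 for 2D input,
#'   volumes in mm^3 for 3D).
#' @export
adiposity_features <- function(sfa_mask, vfa_mask, volume,
                               spacing = rep(1, length(dim(volume))),
                               tpa_mask = NULL) {
  if (!identical(dim(sfa_mask), dim(volume)) ||
      !identical(dim(vfa_mask), dim(volume))) {
    stop_invalid("mask/volume shape mismatch")
  }
  vox <- prod(spacing)
  sfa_a <- sum(sfa_mask) * vox
  vfa_a <- sum(vfa_mask) * vox
  out <- tibble(
    sfa_area = sfa_a,
    vfa_area = vfa_a,
    vfa_sfa_ratio = if (sfa_a > 0) vfa_a / sfa_a else NA_real_,
    sfa_hu_mean = if (sfa_a > 0) mean(volume[sfa_mask]) else NA_real_,
    sfa_hu_sd = if (sum(sfa_mask) > 1) sd(volume[sfa_mask]) else 0,
    vfa_hu_mean = if (vfa_a > 0) mean(volume[vfa_mask]) else NA_real_,
    vfa_hu_sd = if (sum(vfa_mask) > 1) sd(volume[vfa_mask]) else 0
  )
  if (!is.null(tpa_mask)) {
    if (!identical(dim(tpa_mask), dim(volume))) {
      stop_invalid("tpa_mask/volume shape mismatch")
    }
    out$tpa_size <- sum(tpa_mask) * vox
    out$tpa_hu_sd <- if (sum(tpa_mask) > 1) sd(volume[tpa_mask]) else 0
  }
  out
}
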