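#' Simulate a two-class case feature table
#'
#' Draws a case table with Gaussian features in which `n_informative` columns
#' carry a standardized class-mean shift of `effect_size` and the remainder
#' are pure noise. With a single informative feature the theoretical ROC AUC
#' is `pnorm(effect_size / sqrt(2))`, which makes the table a calibrated
#' substrate for end-to-end recovery tests of the modeling pipeline.
#'
#' Within-class correlation is induced by an equicorrelated one-factor model,
#' so each feature keeps unit within-class variance for any `correlation`.
#'
#' @param n_pos,n_neg Number of positive (label 1) and negative (label 0)
#'   cases; both must be at least 1.
#' @param n_features Total number of feature columns `f1..fn`.
#' @param n_informative Number of leading features carrying the class shift;
#'   must not exceed `n_features`.
#' @param effect_size Standardized mean shift `d` (class 1 minus class 0, in
#'   units of the within-class SD) for each informative feature. Must be
#'   nonnegative.
#' @param correlation Within-class correlation between features, in `[0, 1)`.
#' @param seed Integer seed; fixing it makes the table reproducible.
#' @return A tibble with columns `case_id`, `f1..fn`, `label`, `synthetic`
#'   (`FALSE` for all generated rows: these are "real" cases, the synthetic
#'   flag marks SMOTE-interpolated rows downstream).
#' @examples
#' tab <- gen_feature_table(n_pos = 26, n_neg = 81, n_features = 6,
#'                          n_informative = 1, effect_size = 1, seed = 7)
#' nrow(tab)
#' @export
gen_feature_table <- function(n_pos, n_neg, n_features = 6, n_informative = 1,
                              effect_size = 0, correlation = 0, seed = 1) {
  if (n_pos < 1 || n_neg < 1 || n_features < 1) {
    stop_invalid("n_pos, n_neg and n_features must all be >= 1")
  }
  if (n_informative > n_features || n_informative < 0) {
    stop_invalid("n_informative must be between 0 and n_features")
  }
  if (effect_size < 0) stop_invalid("effect_size must be nonnegative")
  if (correlation < 0 || correlation >= 1) {
    stop_invalid("correlation must lie in [0, 1)")
  }
  n <- n_pos + n_neg
  withr::with_seed(seed, {
    z_common <- rnorm(n)
    x <- sqrt(correlation) * matrix(z_common, n, n_features) +
      sqrt(1 - correlation) * matrix(rnorm(n * n_features), n, n_features)
    label <- rep(c(1L, 0L), c(n_pos, n_neg))
    if (n_informative > 0) {
      x[label == 1L, seq_len(n_informative)] <-
        x[label == 1L, seq_len(n_informative), drop = FALSE] + effect_size
    }
    colnames(x) <- paste0("f", seq_len(n_features))
    out <- as_tibble(x)
    out$case_id <- sprintf("case_%04d", seq_len(n))
    out$label <- label
    out$synthetic <- FALSE
    out[, c("case_id", paste0("f", seq_len(n_features)), "label", "synthetic")]
  })
}

# Filled disc/ellipse helper: logical matrix of pixels inside the ellipse.
ellipse_mask <- function(shape, center, radii) {
  r <- outer(seq_len(shape[1]), rep(1, shape[2]))
  c <- outer(rep(1, shape[1]), seq_len(shape[2]))
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 <= 1
}

ellipsoid_mask <- function(shape, center, radii) {
  r <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape)
  c <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]), shape)
  z <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  ((r - center[1]) / radii[1])^2 + ((c - center[2]) / radii[2])^2 +
    ((z - center[3]) / radii[3])^2 <= 1
}

#' Simulate a bilateral mammogram-like image pair
#'
#' Builds a left image containing a half-elliptical "breast" against a dark
#' background (chest wall at the left edge), with a fixed set of symmetric
#' dense blobs, then forms the right image by mirroring about the vertical
#' axis. An `asymmetry` level above zero perturbs the right side only:
#' extra dense blobs whose total area scales with `asymmetry`, and local
#' texture-variance inflation in a patch. Additive Gaussian pixel noise
#' (`noise_sd`) is drawn independently per side.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param asymmetry Nonnegative bilateral asymmetry level; `0` gives an
#'   exactly mirrored pair (up to noise) labelled 0, anything above gives
#'   label 1.
#' @param noise_sd SD of additive Gaussian pixel noise (intensity units;
#'   images use a 0..1 intensity scale).
#' @param seed Integer seed.
#' @return A list with `left`, `right` (numeric matrices), `label` (0/1),
#'   and `truth` (breast mask of the left image, the mirrored right mask,
#'   and the area of asymmetric dense tissue planted on the right).
#' @export
gen_bilateral_pair <- function(shape = c(128L, 96L), asymmetry = 0,
                               noise_sd = 0.01, seed = 1) {
  if (asymmetry < 0) stop_invalid("asymmetry must be nonnegative")
  if (noise_sd < 0) stop_invalid("noise_sd must be nonnegative")
  withr::with_seed(seed, {
    breast <- ellipse_mask(shape, center = c(shape[1] / 2, 1),
                           radii = c(shape[1] * 0.42, shape[2] * 0.72))
    left <- matrix(0, shape[1], shape[2])
    left[breast] <- 0.35
    # symmetric fibroglandular blobs
    blob_spec <- list(
      list(c(0.42, 0.22), 0.07, 0.25),
      list(c(0.55, 0.38), 0.05, 0.20),
      list(c(0.48, 0.55), 0.045, 0.22)
    )
    for (b in blob_spec) {
      m <- ellipse_mask(shape, center = b[[1]] * shape,
                        radii = rep(b[[2]] * shape[1], 2))
      left[m & breast] <- left[m & breast] + b[[3]]
    }
    right <- left[, rev(seq_len(shape[2]))]

    planted_area <- 0L
    if (asymmetry > 0) {
      # extra dense blobs on the right, total area ~ asymmetry
      n_extra <- 1L + floor(asymmetry)
      for (j in seq_len(n_extra)) {
        ctr <- c(runif(1, 0.3, 0.7) * shape[1], runif(1, 0.15, 0.5) * shape[2])
        rad <- sqrt(asymmetry / n_extra) * 0.08 * shape[1]
        m <- ellipse_mask(shape, mirror_center(ctr, shape), rep(rad, 2))
        rb <- breast[, rev(seq_len(shape[2]))]
        right[m & rb] <- right[m & rb] + 0.3
        planted_area <- planted_area + sum(m & rb)
      }
      # local variance inflation in one patch
      patch <- ellipse_mask(shape, mirror_center(c(0.5, 0.35) * shape, shape),
                            rep(0.12 * shape[1], 2))
      rb <- breast[, rev(seq_len(shape[2]))]
      sel <- patch & rb
      right[sel] <- right[sel] + rnorm(sum(sel), 0, 0.05 * asymmetry)
    }
    if (noise_sd > 0) {
      left <- left + matrix(rnorm(prod(shape), 0, noise_sd), shape[1])
      right <- right + matrix(rnorm(prod(shape), 0, noise_sd), shape[1])
    }
    list(left = left, right = right,
         label = as.integer(asymmetry > 0),
         truth = list(breast_mask_left = breast,
                      breast_mask_right = breast[, rev(seq_len(shape[2]))],
                      planted_asymmetric_area = planted_area))
  })
}

mirror_center <- function(center, shape) c(center[1], shape[2] + 1 - center[2])

#' Simulate a lung CT volume with planted emphysema
#'
#' The lung field is an ellipsoid of "normal" lung parenchyma around -820 HU
#' (kept above -920 HU, a >= 30 HU guard band from the -950 HU emphysema
#' threshold). A requested fraction of lung voxels is converted to emphysema:
#' the voxels nearest a set of random blob centers, giving compact blobs with
#' a voxel-exact planted fraction, drawn near -980 HU and clipped below
#' -955 HU so the standard density-mask threshold recovers them exactly.
#'
#' @param shape Volume dimensions `c(nx, ny, nz)`.
#' @param emphysema_fraction Fraction of lung voxels to convert, in `[0, 1]`.
#' @param n_blobs Number of blob seeds used to shape the emphysema region.
#' @param noise_sd SD of additive HU noise (applied inside the guard bands).
#' @param spacing Voxel spacing in mm per axis.
#' @param seed Integer seed.
#' @return A list with `volume` (HU array), `lung_mask`, `emphysema_mask`
#'   (ground truth), `spacing`, and `fraction` (the exact planted fraction).
#' @export
gen_lung_volume <- function(shape = c(40L, 40L, 28L), emphysema_fraction = 0,
                            n_blobs = 4L, noise_sd = 15, spacing = c(1, 1, 1.5),
                            seed = 1) {
  if (emphysema_fraction < 0 || emphysema_fraction > 1) {
    stop_invalid("emphysema_fraction must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    lung <- ellipsoid_mask(shape, center = shape / 2,
                           radii = shape * c(0.42, 0.42, 0.45))
    vol <- array(50, shape)                       # soft tissue background
    n_lung <- sum(lung)
    vol[lung] <- pmin(-820 + rnorm(n_lung, 0, noise_sd), -920 + 60)
    vol[lung] <- pmax(vol[lung], -919)            # guard band above -950

    n_target <- round(emphysema_fraction * n_lung)
    emph <- array(FALSE, shape)
    if (n_target > 0) {
      lung_idx <- which(lung)
      coords <- arrayInd(lung_idx, shape)
      centers <- coords[sample.int(length(lung_idx), n_blobs), , drop = FALSE]
      d2 <- matrix(Inf, length(lung_idx), 1)
      for (b in seq_len(n_blobs)) {
        db <- (coords[, 1] - centers[b, 1])^2 +
          (coords[, 2] - centers[b, 2])^2 +
          ((coords[, 3] - centers[b, 3]) * spacing[3] / spacing[1])^2
        d2 <- pmin(d2, db)
      }
      take <- lung_idx[order(d2)[seq_len(n_target)]]
      emph[take] <- TRUE
      vol[take] <- pmin(-980 + rnorm(n_target, 0, noise_sd), -955)
    }
    list(volume = vol, lung_mask = lung, emphysema_mask = emph,
         spacing = spacing, fraction = if (n_lung > 0) sum(emph) / n_lung else 0)
  })
}

#' Simulate an abdominal CT slice with fat compartments
#'
#' The body is an ellipse of soft tissue (~70 HU, outside the fat window by a
#' >= 30 HU guard band) against air. Subcutaneous fat is planted as the
#' pixel-exact innermost ring adjacent to the body boundary, visceral fat as
#' compact interior blobs separated from the ring by a muscle wall, both
#' drawn around -90 HU and clipped to -130..30 HU (inside the -140..40 HU
#' fat window).
#'
#' @param shape Slice dimensions `c(rows, cols)`.
#' @param sfa_area,vfa_area Requested subcutaneous / visceral fat areas in
#'   mm^2. Must be geometrically feasible for the body ellipse.
#' @param spacing Pixel spacing in mm `c(row, col)`.
#' @param noise_sd SD of additive HU noise.
#' @param n_blobs Number of visceral blob seeds.
#' @param seed Integer seed.
#' @return A list with `image` (HU matrix), `body_mask`, `sfa_mask`,
#'   `vfa_mask` (ground truth), and `spacing`.
#' @export
gen_abdominal_slice <- function(shape = c(120L, 160L), sfa_area = 6000,
                                vfa_area = 2500, spacing = c(2, 2),
                                noise_sd = 8, n_blobs = 3L, seed = 1) {
  if (sfa_area < 0 || vfa_area < 0) stop_invalid("areas must be nonnegative")
  px_area <- prod(spacing)
  withr::with_seed(seed, {
    body <- ellipse_mask(shape, center = shape / 2,
                         radii = shape * c(0.42, 0.44))
    img <- matrix(-1000, shape[1], shape[2])     # air
    img[body] <- pmax(70 + rnorm(sum(body), 0, noise_sd), 65)

    bdist <- boundary_distance(body, spacing)
    n_sfa <- round(sfa_area / px_area)
    n_vfa <- round(vfa_area / px_area)
    body_idx <- which(body)
    ord <- order(bdist[body_idx])
    if (n_sfa > length(body_idx)) stop_invalid("sfa_area exceeds body area")
    sfa <- matrix(FALSE, shape[1], shape[2])
    sfa[body_idx[ord[seq_len(n_sfa)]]] <- TRUE

    # interior region available for visceral fat: leave a >= 3-pixel muscle
    # wall between the subcutaneous ring and any visceral blob
    ring_depth <- if (n_sfa > 0) max(bdist[sfa]) else 0
    wall <- ring_depth + 3 * max(spacing)
    interior_idx <- body_idx[bdist[body_idx] > wall]
    if (n_vfa > length(interior_idx)) {
      stop_invalid("vfa_area does not fit inside the body interior")
    }
    vfa <- matrix(FALSE, shape[1], shape[2])
    if (n_vfa > 0) {
      coords <- arrayInd(interior_idx, shape)
      centers <- coords[sample.int(length(interior_idx), n_blobs), , drop = FALSE]
      d2 <- rep(Inf, length(interior_idx))
      for (b in seq_len(n_blobs)) {
        d2 <- pmin(d2, (coords[, 1] - centers[b, 1])^2 +
                     (coords[, 2] - centers[b, 2])^2)
      }
      vfa[interior_idx[order(d2)[seq_len(n_vfa)]]] <- TRUE
    }
    fat <- sfa | vfa
    img[fat] <- pmin(pmax(-90 + rnorm(sum(fat), 0, noise_sd), -130), 30)
    list(image = img, body_mask = body, sfa_mask = sfa, vfa_mask = vfa,
         spacing = spacing)
  })
}

#' Simulate a pre/post-contrast breast MRI pair
#'
#' The pre-contrast volume holds two half-ellipsoidal breasts (left / right of
#' the midline, anterior to a chest-wall slab) of uniform parenchyma against
#' near-zero air. The post-contrast volume adds a planted enhancement field
#' inside the breast mask plus independent Gaussian noise. The enhancement
#' field is `mean + sd * e`, with `e` standard normal (`skew = 0`) or a
#' standardized right-skewed gamma deviate (`skew > 0`).
#'
#' @param shape Volume dimensions `c(rows, cols, slices)`; rows run
#'   anterior -> posterior.
#' @param enhancement List with elements `mean`, `sd`, `skew` describing the
#'   planted enhancement distribution (enhancement units).
#' @param noise_sd SD of additive acquisition noise on the post volume.
#' @param seed Integer seed.
#' @return A list with `pre`, `post`, `breast_mask`, `left_mask`,
#'   `right_mask`, `chest_wall_row` (first row of the chest-wall slab) and
#'   `truth` (the planted enhancement values, in mask order).
#' @export
gen_mri_pair <- function(shape = c(48L, 64L, 12L),
                         enhancement = list(mean = 0, sd = 0, skew = 0),
                         noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop_invalid("noise_sd must be nonnegative")
  enhancement <- utils::modifyList(list(mean = 0, sd = 0, skew = 0), enhancement)
  withr::with_seed(seed, {
    wall_row <- round(shape[1] * 0.72)
    left <- ellipsoid_mask(shape, center = c(wall_row, shape[2] * 0.28, shape[3] / 2),
                           radii = c(shape[1] * 0.5, shape[2] * 0.2, shape[3] * 0.45))
    right <- ellipsoid_mask(shape, center = c(wall_row, shape[2] * 0.72, shape[3] / 2),
                            radii = c(shape[1] * 0.5, shape[2] * 0.2, shape[3] * 0.45))
    anterior <- array(FALSE, shape)
    anterior[seq_len(wall_row - 1L), , ] <- TRUE
    left <- left & anterior
    right <- right & anterior
    breast <- left | right

    pre <- array(5, shape)                         # air floor
    pre[wall_row:shape[1], , ] <- 400              # chest wall / pectoral slab
    pre[breast] <- 400                             # parenchyma

    n <- sum(breast)
    e <- if (enhancement$skew > 0) {
      shp <- 4 / enhancement$skew^2                # gamma skewness = 2/sqrt(shape)
      (stats::rgamma(n, shape = shp, rate = 1) - shp) / sqrt(shp)
    } else {
      rnorm(n)
    }
    planted <- enhancement$mean + enhancement$sd * e
    post <- pre
    post[breast] <- post[breast] + planted
    if (noise_sd > 0) post <- post + array(rnorm(prod(shape), 0, noise_sd), shape)
    list(pre = pre, post = post, breast_mask = breast,
         left_mask = left, right_mask = right, chest_wall_row = wall_row,
         truth = planted)
  })
}
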