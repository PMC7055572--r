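# Bilateral mammographic asymmetry features.
#
# Six features are computed per side (mean density, fibroglandular area,
# largest focal region in the difference-of-Gaussian map, mean local
# fluctuation, mean DoG response, ordinal density category); the risk model
# consumes their absolute left-right differences.

#' Segment the breast region of a 2D image
#'
#' Thresholds away the dark background and keeps the largest 8-connected
#' foreground component. With `method = "otsu"` the threshold maximises
#' between-class variance; with `method = "quantile"` it is the given
#' intensity quantile, which makes the mask invariant to adding a constant
#' offset to every pixel.
#'
#' @param image Numeric matrix (grayscale image).
#' @param method `"otsu"` or `"quantile"`.
#' @param q Quantile level used when `method = "quantile"`.
#' @return Logical matrix, the breast mask.
#' @export
segment_breast <- function(image, method = c("otsu", "quantile"), q = 0.5) {
  method <- match.arg(method)
  if (!is.matrix(image)) stop_invalid("image must be a 2D matrix")
  thr <- switch(method,
    otsu = otsu_threshold(image),
    quantile = quantile(image, q, names = FALSE)
  )
  fg <- image > thr
  if (!any(fg)) {
    stop_invalid("segmentation found no foreground", class = "imagerisk_empty_segmentation")
  }
  lab <- label_components(fg)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

#' Difference-of-Gaussian map
#'
#' Bandpass response `G(sigma_fine) * image - G(sigma_coarse) * image`
#' computed with separable Gaussian convolution and reflect padding, used to
#' highlight focal dense regions at the scale between the two sigmas.
#'
#' @param image Numeric matrix.
#' @param sigma_fine,sigma_coarse Gaussian SDs in pixels,
#'   `0 < sigma_fine < sigma_coarse`.
#' @return Numeric matrix of the same shape.
#' @export
dog_map <- function(image, sigma_fine = 2, sigma_coarse = 8) {
  if (!(sigma_fine > 0 && sigma_coarse > sigma_fine)) {
    stop_invalid("need 0 < sigma_fine < sigma_coarse")
  }
  gaussian_blur(image, sigma_fine) - gaussian_blur(image, sigma_coarse)
}

#' Local intensity fluctuation map
#'
#' Each pixel is replaced by the sample standard deviation of the intensities
#' in the `window x window` neighbourhood centred on it (reflect padding), a
#' simple local texture-roughness map.
#'
#' @param image Numeric matrix.
#' @param window Odd window size `>= 3` in pixels.
#' @return Numeric matrix of the same shape.
#' @export
fluctuation_map <- function(image, window = 9) {
  if (window < 3 || window %% 2 == 0) {
    stop_invalid("window must be an odd integer >= 3")
  }
  n <- window^2
  s1 <- box_sum(image, window)
  s2 <- box_sum(image^2, window)
  v <- (s2 - s1^2 / n) / (n - 1)
  sqrt(pmax(v, 0))
}

#' Six per-side mammographic features
#'
#' Computes, within the breast mask: (1) mean density (mean intensity);
#' (2) fibroglandular area, the count of dense pixels (above the within-mask
#' Otsu threshold) times the pixel area; (3) focal region size, the area of
#' the largest 8-connected component of the DoG map above its within-mask
#' 99th percentile; (4) mean of the local fluctuation map; (5) mean of the
#' DoG map; (6) an ordinal 1-4 density category from the percent-dense
#' fraction using BIRADS-like quartile bin edges (default 25/50/75%).
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix, the breast mask (same shape, nonempty).
#' @param pixel_area Pixel area in mm^2 (1 = report areas in pixels).
#' @param sigma_fine,sigma_coarse DoG scales, see [dog_map()].
#' @param window Fluctuation window, see [fluctuation_map()].
#' @param focal_quantile Within-mask quantile that thresholds the DoG map.
#' @param category_edges Increasing percent-dense bin edges (length 3)
#'   separating density categories 1..4.
#' @return One-row tibble with columns `mean_density`, `fibroglandular_area`,
#'   `focal_region_size`, `fluctuation_mean`, `dog_mean`, `density_category`.
#' @export
compute_side_features <- function(image, mask, pixel_area = 1,
                                  sigma_fine = 2, sigma_coarse = 8,
                                  window = 9, focal_quantile = 0.99,
                                  category_edges = c(0.25, 0.50, 0.75)) {
  if (!identical(dim(image), dim(mask))) stop_invalid("image/mask shape mismatch")
  if (!any(mask)) {
    stop_invalid("empty breast mask", class = "imagerisk_empty_segmentation")
  }
  vals <- image[mask]
  dense_thr <- otsu_threshold(vals)
  dense <- mask & image > dense_thr
  pct_dense <- sum(dense) / sum(mask)

  dmap <- dog_map(image, sigma_fine, sigma_coarse)
  fthr <- quantile(dmap[mask], focal_quantile, names = FALSE)
  focal <- mask & dmap > fthr
  focal_size <- if (any(focal)) {
    lab <- label_components(focal)
    max(tabulate(lab[lab > 0L])) * pixel_area
  } else 0

  fmap <- fluctuation_map(image, window)

  tibble(
    mean_density = mean(vals),
    fibroglandular_area = sum(dense) * pixel_area,
    focal_region_size = focal_size,
    fluctuation_mean = mean(fmap[mask]),
    dog_mean = mean(dmap[mask]),
    density_category = findInterval(pct_dense, category_edges) + 1L
  )
}

side_feature_names <- c("mean_density", "fibroglandular_area",
                        "focal_region_size", "fluctuation_mean", "dog_mean",
                        "density_category")

#' Bilateral absolute feature differences
#'
#' The asymmetry signature used by the short-term risk model: the
#' elementwise absolute difference `|F_left - F_right|` of the six per-side
#' features. Symmetric in its arguments.
#'
#' @param left,right One-row tibbles (or named lists) of per-side features as
#'   returned by [compute_side_features()].
#' @return One-row tibble with columns `delta_<feature>`.
#' @export
bilateral_difference <- function(left, right) {
  left <- as.list(left)
  right <- as.list(right)
  missing <- setdiff(side_feature_names, intersect(names(left), names(right)))
  if (length(missing) > 0) {
    stop_invalid(paste0("incomplete feature set, missing: ",
                        paste(missing, collapse = ", ")),
                 class = "imagerisk_incomplete_input")
  }
  deltas <- lapply(side_feature_names, function(f) {
    abs(as.numeric(left[[f]]) - as.numeric(right[[f]]))
  })
  names(deltas) <- paste0("delta_", side_feature_names)
  as_tibble(deltas)
}

#' Full bilateral feature extraction for one image pair
#'
#' Convenience wrapper: segments both sides, computes per-side features and
#' returns the bilateral deltas as one case row ready for a case table.
#'
#' @inheritParams compute_side_features
#' @param left,right Numeric matrices, the two sides.
#' @param case_id Case identifier for the output row.
#' @param ... Passed on to [compute_side_features()].
#' @return One-row tibble: `case_id`, `delta_*` columns.
#' @export
extract_mammo_features <- function(left, right, case_id = "case", ...) {
  ml <- segment_breast(left)
  mr <- segment_breast(right)
  fl <- compute_side_features(left, ml, ...)
  fr <- compute_side_features(right, mr, ...)
  out <- bilateral_difference(fl, fr)
  dplyr::bind_cols(tibble(case_id = case_id), out)
}
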