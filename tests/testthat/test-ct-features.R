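# Emphysema density mask, GLCM texture, and the fat compartment split.

test_that("the density mask includes -950 HU and recovers planted fractions", {
  vol <- array(-800, c(4, 4, 2))
  lung <- array(TRUE, c(4, 4, 2))
  vol[1, 1, 1] <- -960
  vol[1, 2, 1] <- -940
  vol[2, 1, 1] <- -950          # threshold is inclusive
  m <- emphysema_mask(vol, lung)
  expect_true(m[1, 1, 1])
  expect_false(m[1, 2, 1])
  expect_true(m[2, 1, 1])

  lv <- gen_lung_volume(emphysema_fraction = 0.10, seed = 8)
  em <- emphysema_mask(lv$volume, lv$lung_mask)
  expect_equal(emphysema_percentage(em, lv$lung_mask, lv$spacing), 0.10,
               tolerance = 0.01 / 0.10)
  # no lung voxel below -950: empty mask
  expect_equal(sum(emphysema_mask(array(-900, c(3, 3, 3)),
                                  array(TRUE, c(3, 3, 3)))), 0)
  expect_error(emphysema_mask(vol, array(FALSE, c(4, 4, 2))),
               class = "imagerisk_empty_segmentation")
})

test_that("emphysema percentage is an exact count ratio with mask checks", {
  lung <- array(FALSE, c(20, 20, 15))
  lung[2:19, 2:19, 2:14] <- TRUE     # a box lung
  emph <- array(FALSE, dim(lung))
  idx <- which(lung)[1:537]
  emph[idx] <- TRUE
  n_lung <- sum(lung)
  expect_equal(emphysema_percentage(emph, lung), 537 / n_lung)
  expect_equal(emphysema_percentage(array(FALSE, dim(lung)), lung), 0)
  expect_equal(emphysema_percentage(lung, lung), 1)
  # spacing cancels when masks scale together
  expect_equal(emphysema_percentage(emph, lung, spacing = c(0.7, 0.7, 2.5)),
               emphysema_percentage(emph, lung))
  bad <- emph
  bad[1, 1, 1] <- TRUE
  expect_error(emphysema_percentage(bad, lung),
               class = "imagerisk_inconsistent_mask")
})

test_that("threshold operators are idempotent and monotone in threshold", {
  lv <- gen_lung_volume(emphysema_fraction = 0.15, seed = 12)
  m1 <- emphysema_mask(lv$volume, lv$lung_mask, -950)
  m2 <- emphysema_mask(lv$volume, m1 | !lv$lung_mask & FALSE | m1, -950)
  expect_identical(emphysema_mask(lv$volume, lv$lung_mask, -950), m1)
  m_lo <- emphysema_mask(lv$volume, lv$lung_mask, -960)
  m_hi <- emphysema_mask(lv$volume, lv$lung_mask, -940)
  expect_true(all(m_lo[m_lo] %in% m1[m_lo]))
  expect_true(all(!(m_lo & !m1)))       # lower threshold shrinks the mask
  expect_true(all(!(m1 & !m_hi)))       # higher threshold grows it
})

test_that("GLCM features match hand-derived small cases", {
  const <- matrix(5, 6, 6)
  g <- glcm_features(const, levels = 8)
  expect_equal(g$glcm_entropy, 0)
  expect_equal(g$glcm_uniformity, 1)
  expect_equal(g$glcm_autocorrelation, 1)

  # 2-level checkerboard, horizontal offset: p(1,2) = p(2,1) = 0.5
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  g2 <- glcm_features(cb, levels = 2, offsets = list(c(0L, 1L)))
  expect_equal(g2$glcm_entropy, 1)
  expect_equal(g2$glcm_uniformity, 0.5)
  expect_equal(g2$glcm_autocorrelation, 2)

  # intensity scaling leaves features unchanged (range quantization)
  withr::with_seed(3, img <- matrix(sample(0:9, 64, TRUE), 8, 8))
  expect_equal(glcm_features(img * 2, levels = 8), glcm_features(img, levels = 8))
})

test_that("GLCM agrees exactly with brute-force pair enumeration", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      img <- matrix(runif(8 * 8, 0, 100), 8, 8)
      mask <- matrix(runif(64) > 0.2, 8, 8)
      offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L), c(0L, 2L))
      p_oracle <- oracle_glcm(img, mask, levels = 6, offsets = offs)
      st <- oracle_glcm_stats(p_oracle)
      g <- glcm_features(img, mask, levels = 6, offsets = offs)
      expect_equal(g$glcm_entropy, st$entropy, tolerance = 1e-12)
      expect_equal(g$glcm_uniformity, st$uniformity, tolerance = 1e-12)
      expect_equal(g$glcm_autocorrelation, st$autocorrelation, tolerance = 1e-12)
    }
    vol <- array(runif(5 * 5 * 4, 0, 10), c(5, 5, 4))
    offs3 <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
    st3 <- oracle_glcm_stats(oracle_glcm(vol, levels = 4, offsets = offs3))
    g3 <- glcm_features(vol, levels = 4, offsets = offs3)
    expect_equal(g3$glcm_entropy, st3$entropy, tolerance = 1e-12)
    expect_equal(g3$glcm_autocorrelation, st3$autocorrelation, tolerance = 1e-12)
  })
})

test_that("the emphysema panel has a stable 21-feature schema and sane shape stats", {
  lv0 <- gen_lung_volume(emphysema_fraction = 0, seed = 4)
  p0 <- emphysema_feature_panel(lv0$volume, lv0$lung_mask, spacing = lv0$spacing)
  expect_equal(ncol(p0), 21)
  expect_equal(p0$emphysema_percentage, 0)
  expect_equal(p0$blob_count, 0L)

  lv <- gen_lung_volume(emphysema_fraction = 0.08, seed = 4)
  p <- emphysema_feature_panel(lv$volume, lv$lung_mask, spacing = lv$spacing)
  expect_identical(names(p), names(p0))
  expect_gt(p$emphysema_percentage, 0.06)
  expect_gte(p$blob_count, 1L)

  # a planted sphere of radius 9 voxels: one blob, sphericity near 1
  vol <- array(-800, c(24, 24, 24))
  lung <- array(TRUE, c(24, 24, 24))
  r2 <- array(0, c(24, 24, 24))
  for (ax in 1:3) {
    idx <- slice.index(r2, ax)
    r2 <- r2 + (idx - 12.5)^2
  }
  vol[r2 <= 81] <- -980
  pp <- emphysema_feature_panel(vol, lung)
  expect_equal(pp$blob_count, 1L)
  expect_equal(pp$largest_blob_sphericity, 1, tolerance = 0.10)
})

test_that("the fat window is inclusive and the SFA/VFA split partitions fat", {
  img <- matrix(70, 10, 10)
  body <- matrix(TRUE, 10, 10)
  img[1, 1] <- -100; img[1, 2] <- 50; img[1, 3] <- -150
  img[1, 4] <- -140; img[1, 5] <- 40
  fm <- fat_mask(img, body)
  expect_true(fm[1, 1]); expect_false(fm[1, 2]); expect_false(fm[1, 3])
  expect_true(fm[1, 4]); expect_true(fm[1, 5])

  ab <- gen_abdominal_slice(sfa_area = 6000, vfa_area = 2500, seed = 13)
  fm2 <- fat_mask(ab$image, ab$body_mask)
  sv <- split_sfa_vfa(fm2, ab$body_mask, spacing = ab$spacing)
  px <- prod(ab$spacing)
  expect_equal(sum(sv$sfa_mask) * px, 6000, tolerance = 0.02)
  expect_equal(sum(sv$vfa_mask) * px, 2500, tolerance = 0.02)
  # exact partition
  expect_identical(sv$sfa_mask | sv$vfa_mask, fm2)
  expect_false(any(sv$sfa_mask & sv$vfa_mask))

  # ring-only phantom: no visceral fat
  ring <- gen_abdominal_slice(sfa_area = 5000, vfa_area = 0, seed = 14)
  rv <- split_sfa_vfa(fat_mask(ring$image, ring$body_mask), ring$body_mask,
                      spacing = ring$spacing)
  expect_equal(sum(rv$vfa_mask), 0)
})

test_that("SFA/VFA partition holds across many random phantoms", {
  withr::with_seed(99, seeds <- sample.int(10000, 12))
  for (s in seeds) {
    ab <- gen_abdominal_slice(sfa_area = runif(1, 2000, 7000),
                              vfa_area = runif(1, 0, 3000), seed = s)
    fm <- fat_mask(ab$image, ab$body_mask)
    sv <- split_sfa_vfa(fm, ab$body_mask, spacing = ab$spacing)
    expect_identical(sv$sfa_mask | sv$vfa_mask, fm)
    expect_false(any(sv$sfa_mask & sv$vfa_mask))
  }
})

test_that("adiposity features report compartment geometry and HU statistics", {
  ab <- gen_abdominal_slice(sfa_area = 6000, vfa_area = 2500, seed = 15,
                            noise_sd = 0)
  f <- adiposity_features(ab$sfa_mask, ab$vfa_mask, ab$image, ab$spacing)
  expect_equal(f$sfa_area, 6000, tolerance = 0.02)
  expect_equal(f$vfa_area, 2500, tolerance = 0.02)
  expect_equal(f$vfa_sfa_ratio, f$vfa_area / f$sfa_area)
  expect_equal(f$sfa_hu_sd, 0, tolerance = 1e-12)   # constant-HU fat
  expect_false("tpa_size" %in% names(f))            # absent without a mask

  empty_vfa <- array(FALSE, dim(ab$image))
  f0 <- adiposity_features(ab$sfa_mask, empty_vfa, ab$image, ab$spacing)
  expect_equal(f0$vfa_area, 0)
  expect_equal(f0$vfa_sfa_ratio, 0)

  tpa <- matrix(FALSE, nrow(ab$image), ncol(ab$image))
  tpa[55:65, 70:90] <- TRUE
  ft <- adiposity_features(ab$sfa_mask, ab$vfa_mask, ab$image, ab$spacing,
                           tpa_mask = tpa)
  expect_equal(ft$tpa_size, sum(tpa) * prod(ab$spacing))
  expect_true(is.finite(ft$tpa_hu_sd))
})
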