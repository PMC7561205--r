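test_that("quantization clips, splits and is monotone", {
  hu <- matrix(c(1, 9, -5, 25), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  q <- quantize(hu, roi, Ng = 2, hu_window = c(0, 10))
  expect_equal(as.vector(q$levels), c(1L, 2L, 1L, 2L))
  q32 <- quantize(matrix(-20, 3, 3), matrix(TRUE, 3, 3), Ng = 32,
                  hu_window = c(-1000, 400))
  expect_true(all(q32$levels == q32$levels[1, 1]))
  # window extremes: at/below low -> 1, at/above high -> Ng
  qe <- quantize(matrix(c(-2000, 400, -1000, 1000), 2, 2),
                 matrix(TRUE, 2, 2), Ng = 32, hu_window = c(-1000, 400))
  expect_equal(as.vector(qe$levels), c(1L, 32L, 1L, 32L))
  expect_error(quantize(hu, roi, Ng = 1), "Ng")
  expect_error(quantize(hu, matrix(FALSE, 2, 2)), "empty")
})

test_that("histogram features match hand arithmetic and printed moments", {
  h <- histogram_features(matrix(1:3, 1), matrix(TRUE, 1, 3))$values
  expect_equal(unname(h[1:3]), c(2, 2 / 3, 1))
  hs <- histogram_features(matrix(c(-1, 0, 1), 1), matrix(TRUE, 1, 3))$values
  expect_equal(unname(hs["hist_skewness"]), 0)
  # kurtosis by direct evaluation of the printed mixed-moment formula
  x <- c(0, 0, 0, 1)
  hk <- histogram_features(matrix(x, 1), matrix(TRUE, 1, 4))$values
  m <- mean(x)
  expect_equal(unname(hk["hist_kurtosis"]),
               (mean((x - m)^4)) / (mean((x - m)^2))^2)
  # constant region: skewness/kurtosis imputed and flagged
  hc <- histogram_features(matrix(5, 2, 2), matrix(TRUE, 2, 2))
  expect_equal(unname(hc$values[c("hist_skewness", "hist_kurtosis")]),
               c(0, 0))
  expect_setequal(hc$imputed, c("hist_skewness", "hist_kurtosis"))
})

test_that("co-occurrence matrix accumulates symmetric in-ROI pairs", {
  q <- quantize(matrix(c(1, 1, 1, 9), 2, 2), matrix(TRUE, 2, 2),
                Ng = 2, hu_window = c(0, 10))
  p <- glcm_matrix(q, c(0L, 1L))
  expect_equal(p, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(sum(p), 1)
  f <- glcm_features(p)
  expect_equal(unname(f["glcm_homogeneity_asm"]), 0.375)
  # constant slice: single-cell matrix, asm 1, contrast 0, entropy 0
  qc <- quantize(matrix(0, 3, 3), matrix(TRUE, 3, 3), Ng = 4,
                 hu_window = c(-10, 10))
  pc <- glcm_matrix(qc, c(1L, 0L))
  fc <- glcm_features(pc)
  expect_equal(unname(fc["glcm_homogeneity_asm"]), 1)
  expect_equal(unname(fc["glcm_contrast"]), 0)
  expect_equal(unname(fc["glcm_entropy"]), 0)
  expect_equal(unname(fc["glcm_variance"]), 0)
  k <- qc$levels[1, 1]
  expect_equal(unname(fc["glcm_sum_average"]), 2 * k)
  # uniform p over Ng^2 cells -> entropy log(Ng^2)
  Ng <- 5
  pu <- matrix(1 / Ng^2, Ng, Ng)
  expect_equal(unname(glcm_features(pu)["glcm_entropy"]), log(Ng^2))
  # ROI-restricted pairs only: masking a pixel removes its pairs
  roi <- matrix(TRUE, 2, 2); roi[2, 2] <- FALSE
  qr <- quantize(matrix(c(1, 1, 1, 9), 2, 2), roi, Ng = 2,
                 hu_window = c(0, 10))
  pr <- glcm_matrix(qr, c(0L, 1L))
  expect_equal(pr[1, 1], 1)   # only the top-row pair remains
})

test_that("run-length features match hand-enumerated runs", {
  q <- quantize(matrix(5, 1, 4), matrix(TRUE, 1, 4), Ng = 4,
                hu_window = c(0, 10))
  f <- rlm_features(q, directions = list(c(0L, 1L)))
  expect_equal(unname(f[c("rlm_sre", "rlm_lre", "rlm_rp")]),
               c(1 / 16, 16, 1 / 4))
  qa <- quantize(matrix(c(1, 9, 1, 9), 1, 4), matrix(TRUE, 1, 4),
                 Ng = 2, hu_window = c(0, 10))
  fa <- rlm_features(qa, directions = list(c(0L, 1L)))
  expect_equal(unname(fa[c("rlm_sre", "rlm_lre", "rlm_rp")]), c(1, 1, 1))
  # all-distinct levels: every pixel its own run in every direction
  qd <- quantize(matrix(c(1, 3, 5, 7), 2, 2), matrix(TRUE, 2, 2),
                 Ng = 8, hu_window = c(0, 8))
  expect_equal(unname(rlm_features(qd)["rlm_rp"]), 1)
  # runs break at the ROI boundary
  roi <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE), 1, 5)
  qb <- quantize(matrix(2, 1, 5), roi, Ng = 2, hu_window = c(0, 10))
  fb <- rlm_features(qb, directions = list(c(0L, 1L)))
  expect_equal(unname(fb["rlm_lre"]), 4)   # two runs of length 2
})

test_that("dependence features follow the neighborhood enumeration", {
  # constant 3x3: s = 3 (corners), 5 (edges), 8 (center)
  qc <- quantize(matrix(0, 3, 3), matrix(TRUE, 3, 3), Ng = 4,
                 hu_window = c(-10, 10))
  f <- ngldm_features(qc, d = 1, a = 0)$values
  s <- c(rep(3, 4), rep(5, 4), 8)
  expect_equal(unname(f["ngldm_sne"]), sum(1 / s^2) / 9)
  expect_equal(unname(f["ngldm_lne"]), sum(s^2) / 9)
  # all-distinct levels with a = 0: every s = 0; SNE sum is empty, LNE 0
  ad <- matrix(seq(0.5, 8.5), 3, 3)
  qcb <- quantize(ad, matrix(TRUE, 3, 3), Ng = 9, hu_window = c(0, 9))
  expect_equal(sort(as.vector(qcb$levels)), 1:9)
  fcb <- ngldm_features(qcb, d = 1, a = 0)$values
  expect_equal(unname(fcb), c(0, 0))
  # a = Ng: all in-ROI neighbors match; equals the brute-force oracle
  qr <- quantize(matrix(runif(25, 0, 10), 5, 5), matrix(TRUE, 5, 5),
                 Ng = 4, hu_window = c(0, 10))
  fr <- ngldm_features(qr, d = 1, a = 4)$values
  expect_equal(unname(fr), oracle_ngldm(qr$levels, 1, 4), tolerance = 1e-12)
  # isolated pixels (no in-ROI neighbor): imputed and flagged
  roi <- matrix(FALSE, 3, 3); roi[1, 1] <- TRUE; roi[3, 3] <- TRUE
  qi <- quantize(matrix(1, 3, 3), roi, Ng = 2, hu_window = c(0, 10))
  fi <- ngldm_features(qi, d = 1, a = 0)
  expect_setequal(fi$imputed, c("ngldm_sne", "ngldm_lne"))
})

test_that("gray-tone difference features handle flat and structured slices", {
  qc <- quantize(matrix(0, 4, 4), matrix(TRUE, 4, 4), Ng = 8,
                 hu_window = c(-10, 10))
  f <- ngtdm_features(qc)$values
  expect_equal(unname(f["ngtdm_coarseness"]), 1e12)
  expect_equal(unname(f["ngtdm_complexity"]), 0)
  expect_equal(unname(f["ngtdm_strength"]), 0)
  # single center deviation on 3x3: equals brute-force evaluation
  hu <- matrix(0, 3, 3); hu[2, 2] <- 8
  qs <- quantize(hu, matrix(TRUE, 3, 3), Ng = 4, hu_window = c(0, 10))
  fs <- ngtdm_features(qs)$values
  expect_equal(unname(fs), oracle_ngtdm(qs$levels, 4), tolerance = 1e-12)
  # two-level half-and-half slice against hand enumeration via the oracle
  hu2 <- cbind(matrix(0, 4, 2), matrix(8, 4, 2))
  qh <- quantize(hu2, matrix(TRUE, 4, 4), Ng = 4, hu_window = c(0, 10))
  fh <- ngtdm_features(qh)$values
  expect_equal(unname(fh), oracle_ngtdm(qh$levels, 4), tolerance = 1e-12)
})

test_that("feature census: 28 features partitioned 5/13/5/2/3", {
  fn <- feature_names()
  gr <- feature_names(groups = TRUE)
  expect_length(fn, 28L)
  expect_equal(as.vector(table(gr)[c("histogram", "glcm", "rlm",
                                     "ngldm", "ngtdm")]),
               c(5L, 13L, 5L, 2L, 3L))
  sf <- slice_features(matrix(rnorm(64, -300, 50), 8, 8),
                       matrix(TRUE, 8, 8))
  expect_identical(names(sf$values), fn)
})

test_that("features are invariant to in-plane translation and histogram to Ng", {
  set.seed(11)
  hu <- matrix(rnorm(36, -200, 80), 6, 6)
  roi <- matrix(runif(36) < 0.9, 6, 6)
  base <- slice_features(hu, roi)$values
  pad <- function(m, fill) {
    out <- matrix(fill, 10, 10)
    out[3:8, 4:9] <- m
    out
  }
  shifted <- slice_features(pad(hu, 0), pad(roi, FALSE))$values
  expect_equal(shifted, base, tolerance = 1e-12)
  # histogram features do not depend on quantization settings
  alt <- slice_features(hu, roi, feature_settings(Ng = 8,
                                                  hu_window = c(-500, 100)))
  expect_equal(alt$values[1:5], base[1:5], tolerance = 1e-12)
})

test_that("extract_samples qualifies slices via the shared mask", {
  sp <- phantom_spec(semi_axes_mm = c(6, 6, 6), texture_amplitude_hu = 0)
  ph <- generate_phantom(sp)
  m0 <- degradation_model(base_noise_sd_hu = 0)
  vol <- render_condition(ph, list(dose_fraction = 1, kernel = "B50f",
                                   thickness_mm = 1), m0, 1)
  mask <- reference_mask(sp, 1)
  fs <- extract_samples(vol, mask, nodule_id = "n", condition_index = 0L)
  expect_true(fs$evaluable)
  # about diameter / thickness slices, within boundary effects
  expect_true(abs(fs$n_slices - 12) <= 2)
  # determinism
  fs2 <- extract_samples(vol, mask, nodule_id = "n", condition_index = 0L)
  expect_identical(fs$features, fs2$features)
  # perfectly flat volume: per-slice SDs 0 and co-occurrence entropy 0
  flat <- image_volume(array(-50, dim(vol$voxels)), vol$spacing_mm)
  ff <- extract_samples(flat, mask)
  expect_true(all(ff$features[, "hist_sd"] == 0))
  expect_true(all(ff$features[, "glcm_entropy"] == 0))
  # a 5 mm reconstruction of a small nodule is non-evaluable
  sps <- phantom_spec(semi_axes_mm = c(3, 3, 3), texture_amplitude_hu = 0)
  vols <- render_condition(generate_phantom(sps),
                           list(dose_fraction = 1, kernel = "B50f",
                                thickness_mm = 5), m0, 1)
  fss <- extract_samples(vols, reference_mask(sps, 5))
  expect_false(fss$evaluable)
  expect_match(fss$reason, "min_slices")
})
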