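small_grid <- condition_grid(doses = c(0.5, 1), kernels = c("B31f", "B50f"),
                             thicknesses = c(1, 3))

test_that("identical sample sets are compatible on all 28 features", {
  ss <- toy_samples(small_grid, "n1")
  cc <- pair_compatibility(ss[[1]], ss[[1]])
  expect_true(cc$evaluable)
  expect_equal(nrow(cc$table), 28L)
  expect_true(all(cc$table$compatible))
  expect_true(all(cc$table$t == 0))
})

test_that("a shifted feature flips only its own compatibility cell", {
  ss <- toy_samples(small_grid, "n1")
  a <- ss[[1]]
  b <- a
  sm <- sample_summary(a)
  se <- sqrt(2 * sm$s["glcm_entropy"]^2 / sm$n)
  b$features[, "glcm_entropy"] <- b$features[, "glcm_entropy"] +
    100 * se
  cc <- pair_compatibility(a, b)
  expect_false(cc$table$compatible[cc$table$feature == "glcm_entropy"])
  expect_equal(sum(!cc$table$compatible), 1L)
  # non-evaluable nodule yields non-evaluable cells, not incompatible ones
  bad <- a
  bad$evaluable <- FALSE
  expect_false(pair_compatibility(a, bad)$evaluable)
})

test_that("compatibility map equals a naive welch_t triple loop", {
  ids <- c("n1", "n2", "n3")
  shift <- function(row, p) 0.4 * (row$dose_fraction == 0.5) +
    0.2 * (row$kernel == "B31f") * (p == 2)
  ss <- toy_samples(small_grid, ids, shift = shift)
  sm <- feature_summaries_from_samples(ss, small_grid)
  cm <- compatibility_map(sm)

  # independent route: welch_t per (pair, feature, patient)
  C <- nrow(small_grid)
  naive <- matrix(0, C, C)
  key <- function(s) paste(s$nodule_id, s$condition_index)
  lut <- setNames(ss, sapply(ss, key))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    num <- 0; den <- 0
    for (p in ids) {
      si <- lut[[paste(p, small_grid$index[i])]]
      sj <- lut[[paste(p, small_grid$index[j])]]
      for (f in feature_names()) {
        tt <- welch_t(mean(si$features[, f]), sd(si$features[, f]),
                      nrow(si$features),
                      mean(sj$features[, f]), sd(sj$features[, f]),
                      nrow(sj$features))
        den <- den + 1
        num <- num + tt$compatible
      }
    }
    naive[i, j] <- 100 * num / den
  }
  expect_equal(unname(cm$cr), naive)
  expect_equal(cm$cr, t(cm$cr))
  expect_true(all(diag(cm$cr) == 100))
  expect_true(all(cm$cr >= 0 & cm$cr <= 100))
})

test_that("exclusions shrink the evaluable denominator instead of scoring false", {
  ids <- c("n1", "n2", "n3")
  ss <- toy_samples(small_grid, ids)
  # exclude nodule 3 at condition index 0
  k <- which(sapply(ss, function(s)
    s$nodule_id == "n3" & s$condition_index == 0))
  ss[[k]]$evaluable <- FALSE
  ss[[k]]$features <- NULL
  sm <- feature_summaries_from_samples(ss, small_grid)
  cm <- compatibility_map(sm)
  expect_equal(cm$n_evaluable[1, 1], 2)    # n3 missing at condition 0
  expect_equal(cm$n_evaluable[2, 2], 3)
  expect_equal(unname(diag(cm$cr)), rep(100, nrow(small_grid)))
})

test_that("marginal robustness counts single-axis pairs correctly", {
  g <- condition_grid()
  expect_equal(nrow(ctcompat:::.axis_pairs(g, "dose")), 480L)
  expect_equal(nrow(ctcompat:::.axis_pairs(g, "kernel")), 1440L)
  expect_equal(nrow(ctcompat:::.axis_pairs(g, "thickness")), 1120L)

  ids <- c("n1", "n2")
  ss <- toy_samples(small_grid, ids)          # no shifts: everything compatible
  sm <- feature_summaries_from_samples(ss, small_grid)
  fr <- marginal_feature_robustness(sm)
  expect_equal(nrow(fr), 28L * 3L)
  expect_true(all(fr$pct_compatible == 100))
  # dose-mean shifts far beyond SE drive dose-axis compatibility to ~0
  ss2 <- toy_samples(small_grid, ids, shift = function(row, p)
    1000 * (row$dose_fraction == 0.5))
  sm2 <- feature_summaries_from_samples(ss2, small_grid)
  fr2 <- marginal_feature_robustness(sm2)
  expect_true(all(fr2$pct_compatible[fr2$axis == "dose"] == 0))
  expect_true(all(fr2$pct_compatible[fr2$axis == "kernel"] == 100))
})

test_that("pairwise axis tables have identity diagonals and expected counts", {
  ids <- c("n1", "n2")
  ss <- toy_samples(small_grid, ids)
  sm <- feature_summaries_from_samples(ss, small_grid)
  axt <- pairwise_axis_tables(sm)
  expect_equal(dim(axt$kernel), c(2L, 2L))
  expect_equal(unname(diag(axt$kernel)), c(100, 100))
  expect_equal(unname(diag(axt$thickness)), c(100, 100))
  expect_equal(unname(diag(axt$dose)), c(100, 100))
  expect_true(all(unlist(axt) >= 0 & unlist(axt) <= 100))
})

test_that("compatibility accounting covers the full comparison census", {
  # 320^2 ordered pairs x 28 features x 23 patients
  expect_identical(comparison_count(nrow(condition_grid()), 28, 23),
                   65945600)
})
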