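# Per-slice texture features: 5 histogram, 13 gray-level co-occurrence
# (GLCM), 5 run-length (RLM), 2 neighboring gray-level dependence (NGLDM)
# and 3 neighborhood gray-tone difference (NGTDM) features, computed on the
# ROI pixels of one axial slice. Histogram features use raw HU; the matrix
# families use a shared monotone quantization so values are comparable
# across reconstruction conditions.

# The four in-plane offsets (row, col) at unit distance: 0, 45, 90, 135
# degrees. Opposite offsets are covered by symmetric accumulation.
.INPLANE_DIRECTIONS <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

#' Canonical feature names
#'
#' The 28 features in their canonical order and grouping: histogram (5),
#' GLCM (13), RLM (5), NGLDM (2), NGTDM (3).
#'
#' @param groups if TRUE return the group of each feature instead.
#' @return character vector of length 28.
#' @export
feature_names <- function(groups = FALSE) {
  nm <- c("hist_mean", "hist_contrast", "hist_sd", "hist_skewness",
          "hist_kurtosis",
          "glcm_homogeneity_asm", "glcm_contrast", "glcm_correlation",
          "glcm_variance", "glcm_idm", "glcm_sum_average",
          "glcm_sum_entropy", "glcm_sum_variance", "glcm_entropy",
          "glcm_difference_variance", "glcm_difference_entropy",
          "glcm_imc1", "glcm_imc2",
          "rlm_sre", "rlm_lre", "rlm_gln", "rlm_rln", "rlm_rp",
          "ngldm_sne", "ngldm_lne",
          "ngtdm_coarseness", "ngtdm_complexity", "ngtdm_strength")
  if (groups)
    rep(c("histogram", "glcm", "rlm", "ngldm", "ngtdm"),
        times = c(5L, 13L, 5L, 2L, 3L))
  else nm
}

#' Feature-extraction settings
#'
#' @param Ng number of gray levels of the shared quantization (default 32).
#' @param hu_window HU window mapped onto 1..Ng (default c(-1000, 400));
#'   identical across all conditions of a study so that level maps are
#'   comparable.
#' @param glcm_distance co-occurrence offset distance in pixels (default 1).
#' @param ngldm_d Chebyshev neighborhood radius of the dependence matrix
#'   (default 1).
#' @param ngldm_a gray-level tolerance for a neighbor to count as dependent
#'   (default 0).
#' @param min_pixels minimum ROI pixels for a slice to qualify (default 10).
#' @param min_slices minimum qualifying slices per nodule/condition
#'   (default 3; the compatibility t-test needs n >= 2, one extra for
#'   stability).
#' @return list of class `feature_settings`.
#' @export
feature_settings <- function(Ng = 32L, hu_window = c(-1000, 400),
                             glcm_distance = 1L, ngldm_d = 1L, ngldm_a = 0L,
                             min_pixels = 10L, min_slices = 3L) {
  if (Ng < 2) stop("Ng must be at least 2")
  if (hu_window[1] >= hu_window[2]) stop("hu_window must satisfy low < high")
  structure(list(Ng = as.integer(Ng), hu_window = as.numeric(hu_window),
                 glcm_distance = as.integer(glcm_distance),
                 ngldm_d = as.integer(ngldm_d),
                 ngldm_a = as.numeric(ngldm_a),
                 min_pixels = as.integer(min_pixels),
                 min_slices = as.integer(min_slices)),
            class = "feature_settings")
}

#' Quantize a slice onto 1..Ng gray levels
#'
#' `level = 1 + floor(Ng * clip((hu - low) / (high - low), 0, 1 - eps))`:
#' HU at or below the window low map to level 1, at or above the high to
#' level Ng; the mapping is monotone and deterministic. Pixels outside the
#' ROI are marked invalid (NA).
#'
#' @param slice_hu numeric matrix of HU values.
#' @param roi_slice logical matrix, same shape.
#' @param Ng number of gray levels (>= 2).
#' @param hu_window length-2 (low, high) HU window.
#' @return object of class `quantized_slice`: list(levels, Ng, hu_window).
#' @export
quantize <- function(slice_hu, roi_slice, Ng = 32L,
                     hu_window = c(-1000, 400)) {
  if (Ng < 2) stop("Ng must be at least 2")
  if (hu_window[1] >= hu_window[2]) stop("hu_window must satisfy low < high")
  stopifnot(identical(dim(slice_hu), dim(roi_slice)))
  if (!any(roi_slice)) stop("ROI slice is empty")
  u <- (slice_hu - hu_window[1]) / (hu_window[2] - hu_window[1])
  u <- pmin(pmax(u, 0), 1 - 1e-12)
  lev <- matrix(1L + as.integer(floor(Ng * u)), nrow = nrow(slice_hu))
  lev[!roi_slice] <- NA_integer_
  structure(list(levels = lev, Ng = as.integer(Ng),
                 hu_window = as.numeric(hu_window)),
            class = "quantized_slice")
}

#' Histogram features of a slice
#'
#' Computed on raw HU of the ROI pixels (independent of quantization).
#' Contrast is the population variance (1/N); the standard deviation uses
#' 1/(N-1); skewness divides the third central moment (1/N) by the sample
#' variance (1/(N-1)) to the 3/2; kurtosis divides the fourth central moment
#' (1/N) by the squared population variance. A constant region leaves
#' skewness and kurtosis undefined; both are imputed 0 and flagged.
#'
#' @param slice_hu,roi_slice as in [quantize()].
#' @return list with `values` (named 5-vector) and `imputed` (names of
#'   imputed features).
#' @export
histogram_features <- function(slice_hu, roi_slice) {
  x <- slice_hu[roi_slice]
  n <- length(x)
  if (n < 2) stop("histogram features need at least 2 ROI pixels")
  m <- mean(x)
  d <- x - m
  contrast <- sum(d^2) / n
  sdev <- sqrt(sum(d^2) / (n - 1))
  imputed <- character(0)
  if (contrast == 0) {
    skew <- 0
    kurt <- 0
    imputed <- c("hist_skewness", "hist_kurtosis")
  } else {
    skew <- (sum(d^3) / n) / (sum(d^2) / (n - 1))^1.5
    kurt <- (sum(d^4) / n) / (sum(d^2) / n)^2
  }
  list(values = c(hist_mean = m, hist_contrast = contrast, hist_sd = sdev,
                  hist_skewness = skew, hist_kurtosis = kurt),
       imputed = imputed)
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts level pairs at the given offset, only when both pixels are inside
#' the ROI, accumulated symmetrically (each pair counted in both orders) and
#' normalized to sum 1.
#'
#' @param quantized a [quantize()] result.
#' @param direction length-2 integer offset (row, col); the four standard
#'   in-plane directions are `list(c(0,1), c(1,1), c(1,0), c(1,-1))`.
#' @param distance offset distance in pixels (default 1).
#' @return Ng x Ng symmetric matrix summing to 1, or NULL when the ROI
#'   contains no valid pair at this offset.
#' @export
glcm_matrix <- function(quantized, direction = c(0L, 1L), distance = 1L) {
  lev <- quantized$levels
  Ng <- quantized$Ng
  dr <- direction[1] * distance
  dc <- direction[2] * distance
  nr <- nrow(lev); nc <- ncol(lev)
  ra <- max(1, 1 - dr):min(nr, nr - dr)
  ca <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(ra) < 1 || length(ca) < 1) return(NULL)
  A <- lev[ra, ca, drop = FALSE]
  B <- lev[ra + dr, ca + dc, drop = FALSE]
  keep <- !is.na(A) & !is.na(B)
  if (!any(keep)) return(NULL)
  cnt <- tabulate((A[keep] - 1L) * Ng + B[keep], Ng * Ng)
  C <- matrix(cnt, Ng, Ng, byrow = TRUE)   # row = first pixel's level
  p <- C + t(C)
  p / sum(p)
}

# index matrices reused across slices, cached per Ng
.glcm_cache <- new.env(parent = emptyenv())
.glcm_idx <- function(Ng) {
  key <- as.character(Ng)
  if (is.null(.glcm_cache[[key]])) {
    iv <- seq_len(Ng)
    .glcm_cache[[key]] <- list(
      iv = iv,
      sum_idx = as.vector(outer(iv, iv, "+")),
      diff_idx = as.vector(abs(outer(iv, iv, "-"))),
      prod_mat = outer(iv, iv),
      inv_diff = 1 / (1 + outer(iv, iv, "-")^2))
  }
  .glcm_cache[[key]]
}

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 13 co-occurrence features of one GLCM
#'
#' Haralick-style features of a symmetric normalized co-occurrence matrix:
#' angular second moment (homogeneity), contrast, correlation, variance,
#' inverse difference moment, sum average/entropy/variance, entropy,
#' difference variance/entropy and the two information measures of
#' correlation. Natural logs; 0 log 0 := 0; correlation := 0 when a marginal
#' SD is zero; IMC1 := 0 when HX = HY = 0.
#'
#' @param p symmetric Ng x Ng matrix summing to 1 (from [glcm_matrix()]).
#' @return named 13-vector.
#' @export
glcm_features <- function(p) {
  Ng <- nrow(p)
  ix <- .glcm_idx(Ng)
  iv <- ix$iv
  px <- rowSums(p)                      # == colSums(p) by symmetry
  mu <- sum(iv * px)
  sig2 <- sum((iv - mu)^2 * px)
  sig <- sqrt(sig2)
  pv <- as.vector(p)
  # marginals of i+j (2..2Ng) and |i-j| (0..Ng-1)
  pxy <- numeric(2 * Ng)
  sums <- rowsum(pv, ix$sum_idx)
  pxy[as.integer(rownames(sums))] <- sums
  pxy <- pxy[2:(2 * Ng)]
  ks <- 2:(2 * Ng)
  pd <- numeric(Ng)
  dsum <- rowsum(pv, ix$diff_idx)
  pd[as.integer(rownames(dsum)) + 1L] <- dsum
  ds <- 0:(Ng - 1)

  asm <- sum(p * p)
  contrast <- sum(ds^2 * pd)
  correlation <- if (sig == 0) 0 else
    (sum(ix$prod_mat * p) - mu * mu) / (sig * sig)
  variance <- sig2
  idm <- sum(ix$inv_diff * p)
  sum_avg <- sum(ks * pxy)
  sum_ent <- -sum(.xlogx(pxy))
  sum_var <- sum((ks - sum_avg)^2 * pxy)
  ent <- -sum(.xlogx(pv))
  mu_d <- sum(ds * pd)
  diff_var <- sum((ds - mu_d)^2 * pd)
  diff_ent <- -sum(.xlogx(pd))
  hx <- -sum(.xlogx(px))
  pxpy <- as.vector(outer(px, px))
  pos <- pv > 0
  hxy1 <- -sum(pv[pos] * log(pxpy[pos]))
  hxy2 <- -sum(.xlogx(pxpy))
  imc1 <- if (hx == 0) 0 else (ent - hxy1) / hx   # max(HX, HY) = HX here
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  c(glcm_homogeneity_asm = asm, glcm_contrast = contrast,
    glcm_correlation = correlation, glcm_variance = variance,
    glcm_idm = idm, glcm_sum_average = sum_avg, glcm_sum_entropy = sum_ent,
    glcm_sum_variance = sum_var, glcm_entropy = ent,
    glcm_difference_variance = diff_var, glcm_difference_entropy = diff_ent,
    glcm_imc1 = imc1, glcm_imc2 = imc2)
}

# Mean of the 13 GLCM features over the four in-plane directions.
# Directions without any valid ROI pair are skipped; if none has a pair the
# 13 features are imputed 0 and flagged.
.glcm_features_slice <- function(quantized, distance = 1L) {
  mats <- lapply(.INPLANE_DIRECTIONS, function(d)
    glcm_matrix(quantized, d, distance))
  mats <- mats[!vapply(mats, is.null, logical(1))]
  nm <- feature_names()[6:18]
  if (length(mats) == 0)
    return(list(values = stats::setNames(rep(0, 13), nm), imputed = nm))
  vals <- rowMeans(vapply(mats, glcm_features, numeric(13)))
  list(values = vals, imputed = character(0))
}

#' Run-length features
#'
#' Runs are maximal segments of equal gray level along a direction,
#' restricted to ROI pixels (a run breaks at the ROI boundary). The five
#' features (short/long run emphasis, gray-level and run-length
#' non-uniformity, run percentage with Np = the slice's ROI pixel count) are
#' computed per direction and averaged.
#'
#' @param quantized a [quantize()] result.
#' @param directions list of offsets (default the four in-plane
#'   directions).
#' @return named 5-vector.
#' @export
rlm_features <- function(quantized, directions = .INPLANE_DIRECTIONS) {
  lev <- quantized$levels
  Ng <- quantized$Ng
  np <- sum(!is.na(lev))
  if (np < 1) stop("run-length features need at least 1 ROI pixel")
  lev0 <- lev
  lev0[is.na(lev0)] <- 0L
  lines_for <- function(d) {
    if (d[1] == 0L) {                 # 0 deg: along columns, per row
      split(lev0, row(lev0))
    } else if (d[2] == 0L) {          # 90 deg: along rows, per column
      split(lev0, col(lev0))
    } else if (d[2] > 0L) {           # 45 deg family: constant col - row
      split(lev0, col(lev0) - row(lev0))
    } else {                          # 135 deg family: constant col + row
      split(lev0, col(lev0) + row(lev0))
    }
  }
  one_dir <- function(d) {
    runs_lev <- integer(0)
    runs_len <- integer(0)
    for (v in lines_for(d)) {
      r <- rle(as.integer(v))
      keep <- r$values > 0L
      runs_lev <- c(runs_lev, r$values[keep])
      runs_len <- c(runs_len, r$lengths[keep])
    }
    nr <- length(runs_len)
    gl_cnt <- tabulate(runs_lev, Ng)
    rl_cnt <- tabulate(runs_len)
    c(rlm_sre = sum(1 / runs_len^2) / nr,
      rlm_lre = sum(runs_len^2) / nr,
      rlm_gln = sum(gl_cnt^2) / nr,
      rlm_rln = sum(rl_cnt^2) / nr,
      rlm_rp = nr / np)
  }
  rowMeans(vapply(directions, one_dir, numeric(5)))
}

# Per-pixel in-ROI neighbor statistics within Chebyshev radius d:
# number of in-ROI neighbors, number whose level differs by <= a, and the
# sum of neighbor levels (for the NGTDM neighborhood mean).
.neighbor_stats <- function(lev, d, a) {
  nr <- nrow(lev); nc <- ncol(lev)
  nbr_in <- matrix(0L, nr, nc)
  match_cnt <- matrix(0L, nr, nc)
  nbr_sum <- matrix(0, nr, nc)
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0 && dc == 0) next
    ra <- max(1, 1 - dr):min(nr, nr - dr)
    ca <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(ra) < 1 || length(ca) < 1) next
    A <- lev[ra, ca, drop = FALSE]
    B <- lev[ra + dr, ca + dc, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    nbr_in[ra, ca] <- nbr_in[ra, ca] + ok
    match_cnt[ra, ca] <- match_cnt[ra, ca] + (ok & !is.na(A - B) &
                                                abs(A - B) <= a)
    Bz <- B
    Bz[!ok] <- 0L
    nbr_sum[ra, ca] <- nbr_sum[ra, ca] + Bz
  }
  list(nbr_in = nbr_in, match_cnt = match_cnt, nbr_sum = nbr_sum)
}

#' Gray-level dependence features
#'
#' For every ROI pixel with at least one in-ROI neighbor within Chebyshev
#' distance `d`, its dependence `s` is the number of such neighbors whose
#' level differs by at most `a`. The dependence table Q(level, s) yields
#' small number emphasis (the 1/s^2 sum runs over s >= 1, where it is
#' defined) and large number emphasis. With no evaluable pixel both features
#' are imputed 0 and flagged.
#'
#' @param quantized a [quantize()] result.
#' @param d neighborhood Chebyshev radius (default 1).
#' @param a gray-level tolerance (default 0).
#' @return list with `values` (named 2-vector) and `imputed`.
#' @export
ngldm_features <- function(quantized, d = 1L, a = 0L) {
  st <- .neighbor_stats(quantized$levels, d, a)
  use <- !is.na(quantized$levels) & st$nbr_in >= 1L
  nm <- c("ngldm_sne", "ngldm_lne")
  if (!any(use))
    return(list(values = stats::setNames(c(0, 0), nm), imputed = nm))
  s <- st$match_cnt[use]
  n <- length(s)
  sne <- sum(ifelse(s >= 1, 1 / s^2, 0)) / n
  lne <- sum(s^2) / n
  list(values = stats::setNames(c(sne, lne), nm), imputed = character(0))
}

#' Gray-tone difference features
#'
#' Amadasun-King coarseness, complexity and texture strength restricted to
#' the ROI: a pixel is valid if it has at least one in-ROI 8-neighbor; its
#' neighborhood mean is taken over the available in-ROI neighbors; s(i) sums
#' |level - neighborhood mean| per level, p_i is the level occurrence
#' probability among valid pixels, and the complexity normalization uses the
#' valid-pixel count. The coarseness denominator is guarded by 1e-12 (a flat
#' region returns the 1e12 cap); strength and complexity of a flat region
#' are 0.
#'
#' @param quantized a [quantize()] result.
#' @return list with `values` (named 3-vector) and `imputed`.
#' @export
ngtdm_features <- function(quantized) {
  lev <- quantized$levels
  Ng <- quantized$Ng
  st <- .neighbor_stats(lev, 1L, 0L)
  use <- !is.na(lev) & st$nbr_in >= 1L
  nm <- c("ngtdm_coarseness", "ngtdm_complexity", "ngtdm_strength")
  if (!any(use))
    return(list(values = stats::setNames(c(0, 0, 0), nm), imputed = nm))
  k <- lev[use]
  amean <- st$nbr_sum[use] / st$nbr_in[use]
  dev <- abs(k - amean)
  s_i <- numeric(Ng)
  acc <- rowsum(dev, k)
  s_i[as.integer(rownames(acc))] <- acc
  n_i <- tabulate(k, Ng)
  n_valid <- sum(n_i)
  p_i <- n_i / n_valid
  denom <- sum(p_i * s_i)
  coarseness <- if (denom > 1e-12) 1 / denom else 1e12
  occ <- which(p_i > 0)
  pi_o <- p_i[occ]
  si_o <- s_i[occ]
  dif <- abs(outer(occ, occ, "-"))
  psum <- outer(pi_o, pi_o, "+")
  pssum <- outer(pi_o * si_o, pi_o * si_o, "+")
  complexity <- sum(dif * pssum / (n_valid * psum))
  s_total <- sum(s_i)
  strength <- if (s_total > 0) sum(psum * dif^2) / s_total else 0
  list(values = stats::setNames(c(coarseness, complexity, strength), nm),
       imputed = character(0))
}

#' All 28 features of one slice
#'
#' @param slice_hu,roi_slice matrices as in [quantize()].
#' @param settings a [feature_settings()].
#' @return list with `values` (named 28-vector in canonical order) and
#'   `imputed` (names of features imputed 0 on this slice).
#' @export
slice_features <- function(slice_hu, roi_slice,
                           settings = feature_settings()) {
  hist_f <- histogram_features(slice_hu, roi_slice)
  q <- quantize(slice_hu, roi_slice, settings$Ng, settings$hu_window)
  glcm_f <- .glcm_features_slice(q, settings$glcm_distance)
  rlm_f <- rlm_features(q)
  ngldm_f <- ngldm_features(q, settings$ngldm_d, settings$ngldm_a)
  ngtdm_f <- ngtdm_features(q)
  values <- c(hist_f$values, glcm_f$values, rlm_f,
              ngldm_f$values, ngtdm_f$values)
  stopifnot(identical(names(values), feature_names()))
  list(values = values,
       imputed = c(hist_f$imputed, glcm_f$imputed, ngldm_f$imputed,
                   ngtdm_f$imputed))
}

#' Extract the per-slice feature sample set of one (nodule, condition)
#'
#' Applies the ROI mask to the volume slice by slice, computes the 28
#' features on every qualifying slice (at least `min_pixels` ROI pixels),
#' and returns them as the sample set feeding the compatibility t-test.
#' Because slice qualification depends only on the shared per-thickness
#' mask, the same slices qualify for all dose/kernel combinations at a
#' thickness. A nodule with fewer than `min_slices` qualifying slices is
#' returned non-evaluable (excluded downstream, not scored incompatible).
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param settings a [feature_settings()].
#' @param nodule_id,condition_index identifiers carried through to tables.
#' @return object of class `feature_samples`: list with `features`
#'   (n_slices x 28 matrix), `imputed` (per-slice comma-separated flags),
#'   `slice_index`, `n_slices`, `evaluable`, `nodule_id`,
#'   `condition_index`.
#' @export
extract_samples <- function(volume, mask, settings = feature_settings(),
                            nodule_id = NA_character_,
                            condition_index = NA_integer_) {
  .check_same_grid(volume, mask)
  nz <- dim(volume$voxels)[3]
  npix <- vapply(seq_len(nz), function(k) sum(mask$voxels[, , k]),
                 numeric(1))
  qualifying <- which(npix >= settings$min_pixels)
  if (length(qualifying) < settings$min_slices) {
    return(structure(list(nodule_id = nodule_id,
                          condition_index = condition_index,
                          features = NULL, imputed = NULL,
                          slice_index = qualifying,
                          n_slices = length(qualifying),
                          evaluable = FALSE,
                          reason = sprintf(
                            "%d qualifying slice(s) < min_slices = %d",
                            length(qualifying), settings$min_slices)),
                     class = "feature_samples"))
  }
  rows <- lapply(qualifying, function(k)
    slice_features(volume$voxels[, , k], mask$voxels[, , k], settings))
  feat <- do.call(rbind, lapply(rows, function(r) r$values))
  rownames(feat) <- NULL
  structure(list(nodule_id = nodule_id, condition_index = condition_index,
                 features = feat,
                 imputed = vapply(rows, function(r)
                   paste(r$imputed, collapse = ";"), character(1)),
                 slice_index = qualifying,
                 n_slices = length(qualifying),
                 evaluable = TRUE, reason = NA_character_),
            class = "feature_samples")
}

#' Per-feature mean/SD/n summary of a sample set
#' @param samples a [extract_samples()] result (must be evaluable).
#' @return list with `m`, `s` (named 28-vectors) and `n` (slice count).
#' @export
sample_summary <- function(samples) {
  stopifnot(inherits(samples, "feature_samples"))
  if (!samples$evaluable) stop("sample set is not evaluable: ",
                               samples$reason)
  list(m = colMeans(samples$features),
       s = apply(samples$features, 2, stats::sd),
       n = samples$n_slices)
}
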