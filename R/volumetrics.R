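# Nodule volumetry across slice thicknesses: per-thickness volumes from the
# reference masks, normalization by the nodule's mean volume, and the
# two-tailed t compatibility analysis of thicknesses.

#' Volume of an ROI mask
#'
#' Count of mask voxels times the voxel volume (in-plane x spacing *
#' in-plane y spacing * thickness).
#'
#' @param mask an [roi_mask()].
#' @return volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  n <- sum(mask$voxels)
  if (n == 0) stop("cannot compute the volume of an empty mask")
  n * prod(mask$spacing_mm)
}

#' Normalize a nodule's per-thickness volumes
#'
#' Each thickness's volume is divided by the nodule's mean volume across the
#' 8 thicknesses, so the normalized volumes average exactly 1 and nodules of
#' different sizes become comparable.
#'
#' @param volumes named numeric vector of per-thickness volumes in mm^3
#'   (names = thickness in mm); all must be present and positive.
#' @param nodule_id identifier.
#' @return object of class `volume_record`: list(nodule_id, thickness_mm,
#'   volume_mm3, v_norm).
#' @export
normalize_volumes <- function(volumes, nodule_id = NA_character_) {
  if (any(is.na(volumes)) || any(volumes <= 0))
    stop("all per-thickness volumes must be present and positive")
  v_norm <- as.numeric(volumes) / mean(volumes)
  structure(list(nodule_id = nodule_id,
                 thickness_mm = as.numeric(names(volumes)),
                 volume_mm3 = as.numeric(volumes),
                 v_norm = v_norm),
            class = "volume_record")
}

#' Two-tailed t compatibility test from summary statistics
#'
#' `t = |m1 - m2| / sqrt(s1^2/n1 + s2^2/n2)`, compared against the 1.96
#' criterion: a pair with t < 1.96 (P < 0.05) is accepted as compatible.
#' The p-value is taken from the standard normal, `2 * (1 - Phi(t))`,
#' consistent with the 1.96/0.05 pairing. Zero-variance conventions: equal
#' means with zero pooled SE give t = 0 (compatible); different means with
#' zero pooled SE give t = Inf (incompatible).
#'
#' @param m1,s1,n1 mean, SD and sample size of the first sample (n >= 2).
#' @param m2,s2,n2 same for the second sample.
#' @return list of class `t_test_result`: m1, m2, s1, s2, n1, n2, t, p,
#'   compatible.
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("welch_t needs n >= 2 in both samples")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  se <- sqrt(s1^2 / n1 + s2^2 / n2)
  t <- if (se == 0) {
    if (m1 == m2) 0 else Inf
  } else abs(m1 - m2) / se
  structure(list(m1 = m1, m2 = m2, s1 = s1, s2 = s2, n1 = n1, n2 = n2,
                 t = t, p = 2 * (1 - stats::pnorm(t)),
                 compatible = t < 1.96),
            class = "t_test_result")
}

#' Thickness compatibility of normalized volumes
#'
#' For every pair of thicknesses, applies the two-tailed t criterion to the
#' across-nodule samples of normalized volume, and summarizes the percent
#' deviation from the mean volume (100 * (V_norm - 1)) per thickness.
#'
#' @param records list of [normalize_volumes()] records (>= 2 nodules), all
#'   covering the same thicknesses.
#' @return list with `p_matrix` (symmetric thickness x thickness p-values,
#'   diagonal 1), `t_matrix`, `compatible` (logical matrix), and
#'   `deviation` (data.frame thickness_mm, mean_pct, sd_pct, n).
#' @export
thickness_compatibility <- function(records) {
  if (length(records) < 2)
    stop("thickness compatibility needs at least 2 nodules")
  th <- records[[1]]$thickness_mm
  vn <- vapply(records, function(r) {
    if (!identical(r$thickness_mm, th))
      stop("volume records cover different thicknesses")
    r$v_norm
  }, numeric(length(th)))               # thickness x nodule
  n <- ncol(vn)
  m <- rowMeans(vn)
  s <- apply(vn, 1, stats::sd)
  k <- length(th)
  tmat <- matrix(0, k, k, dimnames = list(th, th))
  pmat <- matrix(1, k, k, dimnames = list(th, th))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    tt <- welch_t(m[i], s[i], n, m[j], s[j], n)
    tmat[i, j] <- tt$t
    pmat[i, j] <- tt$p
  }
  list(p_matrix = pmat, t_matrix = tmat, compatible = tmat < 1.96,
       deviation = data.frame(thickness_mm = th,
                              mean_pct = 100 * (m - 1),
                              sd_pct = 100 * s,
                              n = n))
}

#' Per-nodule volume records of a simulated cohort
#'
#' Volumes come from the per-thickness reference masks only (segmentation is
#' fixed at the 100%-dose/B50f condition), so dose and kernel never affect
#' volumetry by construction. Nodules with an empty mask at any thickness
#' are excluded with a message.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return list of [normalize_volumes()] records (possibly shorter than the
#'   cohort when nodules were excluded).
#' @export
cohort_volume_records <- function(cohort) {
  stopifnot(inherits(cohort, "ct_cohort"))
  recs <- list()
  for (i in seq_along(cohort$nodule_ids)) {
    ms <- cohort$masks[[i]]
    if (any(vapply(ms, function(m) m$empty, logical(1)))) {
      message("nodule ", cohort$nodule_ids[i],
              " excluded from volumetry: empty mask at some thickness")
      next
    }
    vols <- vapply(ms, mask_volume, numeric(1))
    recs[[length(recs) + 1L]] <-
      normalize_volumes(vols, nodule_id = cohort$nodule_ids[i])
  }
  recs
}
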