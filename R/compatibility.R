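# The compatibility ratio and its maps: for a pair of reconstruction
# conditions, the fraction of (feature, patient) cells whose two-tailed t
# statistic (computed from the per-slice feature samples of each condition)
# falls below 1.96, expressed in percent. The full map covers every ordered
# condition pair including the diagonal.

.T_CRIT <- 1.96

#' Feature compatibility of one condition pair for one nodule
#'
#' Applies the two-tailed t criterion feature by feature to the per-slice
#' sample vectors of the two conditions. A nodule excluded at either
#' condition yields non-evaluable cells (not scored incompatible).
#'
#' @param samples_i,samples_j [extract_samples()] results for the same
#'   nodule under two conditions.
#' @return object of class `compatibility_cell`: list(evaluable, table)
#'   where `table` is a data.frame(feature, t, compatible).
#' @export
pair_compatibility <- function(samples_i, samples_j) {
  stopifnot(inherits(samples_i, "feature_samples"),
            inherits(samples_j, "feature_samples"))
  if (!isTRUE(all.equal(samples_i$nodule_id, samples_j$nodule_id)))
    stop("sample sets belong to different nodules")
  if (!samples_i$evaluable || !samples_j$evaluable)
    return(structure(list(evaluable = FALSE, table = NULL),
                     class = "compatibility_cell"))
  a <- sample_summary(samples_i)
  b <- sample_summary(samples_j)
  se <- sqrt(a$s^2 / a$n + b$s^2 / b$n)
  d <- abs(a$m - b$m)
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf))
  structure(list(evaluable = TRUE,
                 table = data.frame(feature = feature_names(),
                                    t = unname(t),
                                    compatible = unname(t < .T_CRIT),
                                    stringsAsFactors = FALSE)),
            class = "compatibility_cell")
}

#' Summarize a per-slice feature table into per-condition statistics
#'
#' @param tab data.frame with columns nodule_id, condition_index,
#'   slice_index and the 28 feature columns (the pipeline's feature table).
#' @param grid the condition grid the table was extracted under.
#' @return object of class `feature_summaries`: arrays `m`, `s`
#'   (condition x feature x nodule), `n` and `evaluable`
#'   (condition x nodule), plus `grid` and `nodule_ids`. A (condition,
#'   nodule) cell absent from the table is marked non-evaluable.
#' @export
feature_summaries <- function(tab, grid) {
  fn <- feature_names()
  if (!all(c("nodule_id", "condition_index", fn) %in% names(tab)))
    stop("feature table lacks required columns")
  ids <- sort(unique(tab$nodule_id))
  C <- nrow(grid)
  P <- length(ids)
  m <- array(NA_real_, dim = c(C, 28L, P),
             dimnames = list(NULL, fn, ids))
  s <- m
  n <- matrix(0L, C, P, dimnames = list(NULL, ids))
  ev <- matrix(FALSE, C, P, dimnames = list(NULL, ids))
  ci <- match(tab$condition_index, grid$index)
  if (any(is.na(ci)))
    stop("feature table contains condition indices outside the grid")
  pi <- match(tab$nodule_id, ids)
  grp <- interaction(ci, pi, drop = TRUE)
  fm <- as.matrix(tab[, fn])
  for (g in levels(grp)) {
    rows <- which(grp == g)
    cc <- ci[rows[1]]
    pp <- pi[rows[1]]
    m[cc, , pp] <- colMeans(fm[rows, , drop = FALSE])
    s[cc, , pp] <- apply(fm[rows, , drop = FALSE], 2, stats::sd)
    n[cc, pp] <- length(rows)
    ev[cc, pp] <- TRUE
  }
  structure(list(m = m, s = s, n = n, evaluable = ev, grid = grid,
                 nodule_ids = ids),
            class = "feature_summaries")
}

#' Build feature summaries from a list of sample sets
#' @param samples_list flat list of [extract_samples()] results covering
#'   (nodule, condition) cells; non-evaluable sets are kept as exclusions.
#' @param grid the condition grid.
#' @return a [feature_summaries()] object.
#' @export
feature_summaries_from_samples <- function(samples_list, grid) {
  ev_sets <- Filter(function(x) x$evaluable, samples_list)
  if (length(ev_sets) == 0) stop("no evaluable sample sets")
  tab <- do.call(rbind, lapply(ev_sets, function(x) {
    df <- as.data.frame(x$features)
    df$nodule_id <- x$nodule_id
    df$condition_index <- x$condition_index
    df$slice_index <- x$slice_index
    df
  }))
  feature_summaries(tab, grid)
}

# Per-(feature, patient) compatibility booleans for a set of condition row
# pairs, accumulated into numerator/denominator counts. `pairs` is a 2-column
# matrix of row indices into the grid.
.pair_counts <- function(sm, pairs) {
  P <- length(sm$nodule_ids)
  npair <- nrow(pairs)
  num <- matrix(0, npair, 28L)
  den <- matrix(0, npair, 28L)
  ev2 <- sm$evaluable[pairs[, 1], , drop = FALSE] &
         sm$evaluable[pairs[, 2], , drop = FALSE]     # npair x P
  for (f in seq_len(28L)) {
    mi <- sm$m[, f, , drop = FALSE][pairs[, 1], 1, , drop = FALSE]
    mj <- sm$m[, f, , drop = FALSE][pairs[, 2], 1, , drop = FALSE]
    vi <- (sm$s[, f, , drop = FALSE][pairs[, 1], 1, , drop = FALSE])^2 /
      array(sm$n[pairs[, 1], ], dim = c(npair, 1, P))
    vj <- (sm$s[, f, , drop = FALSE][pairs[, 2], 1, , drop = FALSE])^2 /
      array(sm$n[pairs[, 2], ], dim = c(npair, 1, P))
    d <- abs(mi - mj)
    se <- sqrt(vi + vj)
    comp <- (d < .T_CRIT * se) | (se == 0 & d == 0)
    comp <- matrix(comp, npair, P)
    comp[!ev2] <- FALSE
    num[, f] <- rowSums(comp)
    den[, f] <- rowSums(ev2)
  }
  list(num = num, den = den)   # npair x 28
}

#' Compatibility map over a condition grid
#'
#' The map entry for conditions (R_i, R_j) is the percentage of evaluable
#' (feature, patient) cells whose t statistic is below 1.96. With every cell
#' evaluable the denominator is 28 x n_patients; when nodules are excluded
#' at a condition (too few qualifying slices) the denominator shrinks to the
#' evaluable cells. The matrix is symmetric with a 100% diagonal on fully
#' evaluable cohorts.
#'
#' @param sm a [feature_summaries()] object.
#' @return object of class `compatibility_map`: list(cr, n_evaluable, grid,
#'   sort_order) where `cr` is the n_cond x n_cond percentage matrix.
#' @export
compatibility_map <- function(sm) {
  stopifnot(inherits(sm, "feature_summaries"))
  grid <- sm$grid
  C <- nrow(grid)
  if (C == 0) stop("empty condition grid")
  P <- length(sm$nodule_ids)
  num <- matrix(0, C, C)
  evmat <- matrix(0, C, C)
  for (p in seq_len(P))
    evmat <- evmat + outer(sm$evaluable[, p], sm$evaluable[, p], "&")
  den <- 28 * evmat
  for (f in seq_len(28L)) for (p in seq_len(P)) {
    if (!any(sm$evaluable[, p])) next
    m <- sm$m[, f, p]
    v <- sm$s[, f, p]^2 / sm$n[, p]
    m[!sm$evaluable[, p]] <- 0
    v[!sm$evaluable[, p]] <- 0
    d <- abs(outer(m, m, "-"))
    se <- sqrt(outer(v, v, "+"))
    comp <- (d < .T_CRIT * se) | (se == 0 & d == 0)
    pm <- outer(sm$evaluable[, p], sm$evaluable[, p], "&")
    num <- num + (comp & pm)
  }
  cr <- ifelse(den > 0, 100 * num / den, NA_real_)
  lab <- condition_label(grid)
  dimnames(cr) <- list(lab, lab)
  structure(list(cr = cr, n_evaluable = evmat, grid = grid,
                 sort_order = condition_sort_order(grid)),
            class = "compatibility_map")
}

# unordered pairs of grid row indices differing only along `axis`
.axis_pairs <- function(grid, axis) {
  fixed <- switch(axis,
                  dose = c("kernel", "thickness_mm"),
                  kernel = c("dose_fraction", "thickness_mm"),
                  thickness = c("dose_fraction", "kernel"))
  key <- do.call(paste, c(grid[fixed], sep = "|"))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) >= 2) {
      cmb <- utils::combn(rows, 2)
      out[[k]] <- t(cmb)
    }
  }
  do.call(rbind, out)
}

#' Per-feature robustness against single-axis changes
#'
#' For each feature and each axis (dose, kernel, thickness): the percentage
#' of compatible (pair, patient) cells over all unordered condition pairs
#' that differ only along that axis. On the full grid there are 480
#' dose-only, 1440 kernel-only and 1120 thickness-only pairs.
#'
#' @param sm a [feature_summaries()] object.
#' @return data.frame(feature, group, axis, pct_compatible, n_pairs).
#' @export
marginal_feature_robustness <- function(sm) {
  out <- list()
  for (axis in c("dose", "kernel", "thickness")) {
    pairs <- .axis_pairs(sm$grid, axis)
    if (is.null(pairs)) next
    cnt <- .pair_counts(sm, pairs)
    out[[axis]] <- data.frame(
      feature = feature_names(),
      group = feature_names(groups = TRUE),
      axis = axis,
      pct_compatible = 100 * colSums(cnt$num) / pmax(colSums(cnt$den), 1),
      n_pairs = nrow(pairs),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise single-axis compatibility tables
#'
#' For every unordered pair of values on one axis (kernel, thickness or
#' dose), the mean percentage of compatible features over all patients and
#' all fixed settings of the other two axes (on the full grid: 32 fixed
#' settings for kernel pairs, 40 for thickness pairs, 80 for dose pairs).
#' Diagonal entries compare a condition with itself and are 100%.
#'
#' @param sm a [feature_summaries()] object.
#' @return named list of three symmetric percentage matrices: `kernel`,
#'   `thickness`, `dose`.
#' @export
pairwise_axis_tables <- function(sm) {
  grid <- sm$grid
  make_table <- function(col, values) {
    k <- length(values)
    tab <- matrix(NA_real_, k, k, dimnames = list(values, values))
    other <- setdiff(c("dose_fraction", "kernel", "thickness_mm"), col)
    key <- do.call(paste, c(grid[other], sep = "|"))
    for (i in seq_len(k)) for (j in i:k) {
      ri <- which(grid[[col]] == values[i])
      rj <- which(grid[[col]] == values[j])
      mi <- match(key[rj], key[ri])   # align fixed settings
      ok <- !is.na(mi)
      pairs <- cbind(ri[mi[ok]], rj[ok])
      if (i == j) pairs <- pairs[pairs[, 1] == pairs[, 2], , drop = FALSE]
      if (nrow(pairs) == 0) next
      cnt <- .pair_counts(sm, pairs)
      tot_den <- sum(cnt$den)
      tab[i, j] <- tab[j, i] <-
        if (tot_den > 0) 100 * sum(cnt$num) / tot_den else NA_real_
    }
    tab
  }
  list(kernel = make_table("kernel",
                           intersect(.SORT_KERNEL, unique(grid$kernel))),
       thickness = make_table("thickness_mm",
                              intersect(.SORT_THICKNESS,
                                        unique(grid$thickness_mm))),
       dose = make_table("dose_fraction",
                         intersect(.SORT_DOSE, unique(grid$dose_fraction))))
}
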