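# Brute-force oracles: direct loop evaluation of the printed feature
# definitions over exhaustively enumerated pairs / runs / neighborhoods.
# Deliberately naive and independent of the package's vectorized path.

DIRS4 <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

oracle_hist <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss2 <- sum((x - m)^2)
  contrast <- ss2 / n
  sdev <- sqrt(ss2 / (n - 1))
  if (ss2 == 0) {
    skew <- 0; kurt <- 0
  } else {
    skew <- (sum((x - m)^3) / n) / (ss2 / (n - 1))^1.5
    kurt <- (sum((x - m)^4) / n) / (ss2 / n)^2
  }
  c(m, contrast, sdev, skew, kurt)
}

# symmetric normalized co-occurrence matrix by pair enumeration
oracle_glcm_matrix <- function(lev, Ng, dir, distance = 1L) {
  C <- matrix(0, Ng, Ng)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dir[1] * distance
    c2 <- c + dir[2] * distance
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- lev[r, c]; b <- lev[r2, c2]
    if (is.na(a) || is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  if (sum(C) == 0) return(NULL)
  C / sum(C)
}

oracle_glcm_features <- function(p) {
  Ng <- nrow(p)
  px <- sapply(seq_len(Ng), function(i) sum(p[i, ]))
  py <- sapply(seq_len(Ng), function(j) sum(p[, j]))
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  pxy <- numeric(2 * Ng)          # p_{x+y}(k), k = 2..2Ng
  pd <- numeric(Ng)               # p_{x-y}(k), k = 0..Ng-1
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    pxy[i + j] <- pxy[i + j] + p[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
  }
  xlx <- function(v) if (v > 0) v * log(v) else 0
  asm <- 0; idm <- 0; ent <- 0; corr_num <- 0; varia <- 0
  hxy1 <- 0; hxy2 <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    asm <- asm + p[i, j]^2
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    ent <- ent - xlx(p[i, j])
    corr_num <- corr_num + i * j * p[i, j]
    varia <- varia + (i - mux)^2 * p[i, j]
    if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log(px[i] * py[j])
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - xlx(px[i] * py[j])
  }
  contrast <- 0
  for (n in 0:(Ng - 1)) contrast <- contrast + n^2 * pd[n + 1]
  correlation <- if (sigx == 0 || sigy == 0) 0 else
    (corr_num - mux * muy) / (sigx * sigy)
  sum_avg <- 0; sum_ent <- 0
  for (k in 2:(2 * Ng)) {
    sum_avg <- sum_avg + k * pxy[k]
    sum_ent <- sum_ent - xlx(pxy[k])
  }
  sum_var <- 0
  for (k in 2:(2 * Ng)) sum_var <- sum_var + (k - sum_avg)^2 * pxy[k]
  mud <- sum((0:(Ng - 1)) * pd)
  diff_var <- sum(((0:(Ng - 1)) - mud)^2 * pd)
  diff_ent <- -sum(sapply(pd, xlx))
  hx <- -sum(sapply(px, xlx)); hy <- -sum(sapply(py, xlx))
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(asm, contrast, correlation, varia, idm, sum_avg, sum_ent, sum_var,
    ent, diff_var, diff_ent, imc1, imc2)
}

oracle_glcm_avg <- function(lev, Ng, distance = 1L, dirs = DIRS4) {
  mats <- lapply(dirs, function(d)
    oracle_glcm_matrix(lev, Ng, d, distance))
  mats <- mats[!sapply(mats, is.null)]
  if (length(mats) == 0) return(rep(0, 13))
  rowMeans(sapply(mats, oracle_glcm_features))
}

# walk every line of the slice in a direction, collecting maximal runs
oracle_rlm <- function(lev, Ng, dirs = DIRS4) {
  nr <- nrow(lev); nc <- ncol(lev)
  np <- sum(!is.na(lev))
  one <- function(d) {
    starts <- list()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      pr <- r - d[1]; pc <- c - d[2]
      if (pr < 1 || pr > nr || pc < 1 || pc > nc)
        starts[[length(starts) + 1]] <- c(r, c)
    }
    runs_lev <- integer(0); runs_len <- integer(0)
    for (s in starts) {
      r <- s[1]; c <- s[2]
      cur <- NA_integer_; len <- 0L
      while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
        v <- lev[r, c]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1L
        } else {
          if (!is.na(cur) && len > 0) {
            runs_lev <- c(runs_lev, cur); runs_len <- c(runs_len, len)
          }
          cur <- v; len <- if (is.na(v)) 0L else 1L
        }
        r <- r + d[1]; c <- c + d[2]
      }
      if (!is.na(cur) && len > 0) {
        runs_lev <- c(runs_lev, cur); runs_len <- c(runs_len, len)
      }
    }
    nruns <- length(runs_len)
    sre <- sum(1 / runs_len^2) / nruns
    lre <- sum(runs_len^2) / nruns
    gln <- sum(sapply(seq_len(Ng), function(g)
      sum(runs_lev == g)^2)) / nruns
    rln <- sum(sapply(seq_len(max(runs_len)), function(l)
      sum(runs_len == l)^2)) / nruns
    rp <- nruns / np
    c(sre, lre, gln, rln, rp)
  }
  rowMeans(sapply(dirs, one))
}

oracle_ngldm <- function(lev, d = 1L, a = 0L) {
  nr <- nrow(lev); nc <- ncol(lev)
  svals <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lev[r, c])) next
    nbr <- 0L; s <- 0L
    for (dr in -d:d) for (dc in -d:d) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(lev[r2, c2])) next
      nbr <- nbr + 1L
      if (abs(lev[r2, c2] - lev[r, c]) <= a) s <- s + 1L
    }
    if (nbr >= 1) svals <- c(svals, s)
  }
  if (length(svals) == 0) return(c(0, 0))
  n <- length(svals)
  sne <- sum(ifelse(svals >= 1, 1 / svals^2, 0)) / n
  lne <- sum(svals^2) / n
  c(sne, lne)
}

oracle_ngtdm <- function(lev, Ng) {
  nr <- nrow(lev); nc <- ncol(lev)
  ks <- integer(0); devs <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lev[r, c])) next
    tot <- 0; cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(lev[r2, c2])) next
      tot <- tot + lev[r2, c2]; cnt <- cnt + 1L
    }
    if (cnt >= 1) {
      ks <- c(ks, lev[r, c])
      devs <- c(devs, abs(lev[r, c] - tot / cnt))
    }
  }
  if (length(ks) == 0) return(c(0, 0, 0))
  nv <- length(ks)
  s_i <- sapply(seq_len(Ng), function(g) sum(devs[ks == g]))
  p_i <- sapply(seq_len(Ng), function(g) sum(ks == g)) / nv
  den <- sum(p_i * s_i)
  coars <- if (den > 1e-12) 1 / den else 1e12
  cmplx <- 0; str_num <- 0
  for (i in seq_len(Ng)) for (j in seq_len(Ng)) {
    if (p_i[i] > 0 && p_i[j] > 0) {
      cmplx <- cmplx + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (nv * (p_i[i] + p_i[j]))
      str_num <- str_num + (p_i[i] + p_i[j]) * (i - j)^2
    }
  }
  strength <- if (sum(s_i) > 0) str_num / sum(s_i) else 0
  c(coars, cmplx, strength)
}

# random quantized test slice (<= 8x8) with a random ROI
random_slice <- function(seed) {
  set.seed(seed)
  nr <- sample(3:8, 1); nc <- sample(3:8, 1)
  Ng <- sample(3:8, 1)
  hu <- matrix(runif(nr * nc, -900, 300), nr, nc)
  roi <- matrix(runif(nr * nc) < 0.85, nr, nc)
  if (sum(roi) < 4) roi[sample(nr * nc, 4)] <- TRUE
  list(hu = hu, roi = roi, Ng = Ng, window = c(-1000, 400))
}

# cohort of hand-built sample sets for compatibility tests: features are
# deterministic per (condition, nodule) with controllable shifts
toy_samples <- function(grid, nodule_ids, n_slices = 5, shift = NULL,
                        seed = 42) {
  set.seed(seed)
  out <- list()
  for (p in seq_along(nodule_ids)) {
    base <- matrix(rnorm(28, sd = 5), nrow = 1)
    # slice-level scatter frozen per nodule: conditions without a shift
    # carry identical samples (compatible by construction)
    scatter <- matrix(rnorm(n_slices * 28, sd = 0.1), n_slices)
    for (ci in seq_len(nrow(grid))) {
      m <- matrix(rep(base, n_slices), nrow = n_slices, byrow = TRUE) +
        scatter
      if (!is.null(shift)) m <- m + shift(grid[ci, ], p)
      colnames(m) <- feature_names()
      out[[length(out) + 1]] <- structure(
        list(nodule_id = nodule_ids[p], condition_index = grid$index[ci],
             features = m, imputed = rep("", n_slices),
             slice_index = seq_len(n_slices), n_slices = n_slices,
             evaluable = TRUE, reason = NA_character_),
        class = "feature_samples")
    }
  }
  out
}
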