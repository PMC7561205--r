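# Synthetic nodule phantoms and their rendering under a reconstruction
# condition. The degradation chain is an image-domain surrogate for the
# acquisition/reconstruction physics: kernel-dependent in-plane Gaussian
# blur, slab (partial-volume) averaging across the slice thickness, and
# white Gaussian quantum noise whose SD scales as dose^(-1/2) and
# thickness^(-1/2).

#' Default reconstruction-kernel surrogate table
#'
#' Image-domain stand-ins for the ten protocol kernels. Within each family
#' sharpness increases with the kernel number: blur_sigma_mm decreases and
#' the noise gain increases. `base_gain` for the iterative (I) family is the
#' pre-iterative-reconstruction value; the effective noise gain of an I
#' kernel is `base_gain * ir_noise_factor` of the degradation model, which
#' encodes the noise suppression of iterative reconstruction at matched
#' sharpness.
#'
#' @return data.frame with columns kernel, family ("B" or "I"),
#'   blur_sigma_mm, base_gain.
#' @export
kernel_table <- function() {
  data.frame(
    kernel = c("B31f", "B40f", "B50f", "B60f", "B70f",
               "I26f", "I31f", "I40f", "I50f", "I70f"),
    family = rep(c("B", "I"), each = 5L),
    blur_sigma_mm = c(1.2, 0.9, 0.7, 0.5, 0.35,
                      1.4, 1.2, 0.9, 0.7, 0.35),
    base_gain = c(0.7, 0.85, 1.0, 1.4, 2.0,
                  0.6, 0.7, 0.85, 1.0, 2.0),
    stringsAsFactors = FALSE)
}

#' Image-domain degradation model
#'
#' Bundles the noise/blur parameters used when rendering a phantom under a
#' reconstruction condition. At 100% dose, B50f kernel and 1 mm thickness
#' the background noise SD equals `base_noise_sd_hu`; other conditions scale
#' it by `noise_gain(kernel) * dose_fraction^(-1/2) * thickness_mm^(-1/2)`.
#'
#' @param base_noise_sd_hu noise SD in HU at dose 1.0 / B50f / 1 mm
#'   (default 12).
#' @param kernels kernel surrogate table, see [kernel_table()].
#' @param ir_noise_factor multiplicative noise suppression of the iterative
#'   family, in (0, 1] (default 0.7).
#' @return object of class `degradation_model`.
#' @export
degradation_model <- function(base_noise_sd_hu = 12,
                              kernels = kernel_table(),
                              ir_noise_factor = 0.7) {
  stopifnot(base_noise_sd_hu >= 0, is.data.frame(kernels))
  if (!(ir_noise_factor > 0 && ir_noise_factor <= 1))
    stop("ir_noise_factor must be in (0, 1]")
  need <- c("kernel", "family", "blur_sigma_mm", "base_gain")
  if (!all(need %in% names(kernels)))
    stop("kernel table must have columns ", paste(need, collapse = ", "))
  gain <- kernels$base_gain *
    ifelse(kernels$family == "I", ir_noise_factor, 1)
  for (fam in unique(kernels$family)) {
    sel <- kernels$family == fam
    if (any(diff(gain[sel]) <= 0))
      stop("noise gain must strictly increase with sharpness in family ", fam)
    if (any(diff(kernels$blur_sigma_mm[sel]) >= 0))
      stop("blur sigma must strictly decrease with sharpness in family ", fam)
  }
  structure(list(base_noise_sd_hu = base_noise_sd_hu,
                 kernels = kernels,
                 ir_noise_factor = ir_noise_factor),
            class = "degradation_model")
}

.kernel_row <- function(model, kernel) {
  i <- match(kernel, model$kernels$kernel)
  if (is.na(i)) stop("unknown kernel label: ", kernel)
  model$kernels[i, ]
}

#' Effective noise gain of a kernel
#' @param model a [degradation_model()].
#' @param kernel kernel label.
#' @return scalar noise gain (iterative kernels include ir_noise_factor).
#' @export
noise_gain <- function(model, kernel) {
  row <- .kernel_row(model, kernel)
  row$base_gain * if (row$family == "I") model$ir_noise_factor else 1
}

#' Rendered noise SD for a condition
#' @inheritParams noise_gain
#' @param dose_fraction,thickness_mm condition parameters.
#' @return Gaussian noise SD in HU.
#' @export
noise_sd <- function(model, dose_fraction, kernel, thickness_mm) {
  model$base_noise_sd_hu * noise_gain(model, kernel) *
    dose_fraction^(-0.5) * (thickness_mm / 1.0)^(-0.5)
}

#' Specification of one synthetic nodule phantom
#'
#' A solid ellipsoidal nodule with band-limited internal texture embedded in
#' a lung-density background. All lengths are mm, all intensities HU.
#'
#' @param nodule_center_mm 3-vector, nodule center in the field of view.
#' @param semi_axes_mm 3-vector of ellipsoid semi-axes, each in [2, 12.5].
#' @param nodule_mean_hu mean nodule attenuation (default -50).
#' @param background_mean_hu lung background attenuation (default -850).
#' @param texture_amplitude_hu SD of the internal texture field (default 40).
#' @param texture_correlation_mm correlation length of the texture
#'   (default 2.5).
#' @param field_of_view_mm 3-vector (default 36 mm cube).
#' @param in_plane_spacing_mm in-plane voxel spacing (default 0.7).
#' @param seed integer freezing the texture field (texture is anatomy: it is
#'   fixed per nodule, while acquisition noise varies per rendering).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(nodule_center_mm = c(18, 18, 18),
                         semi_axes_mm = c(8, 8, 8),
                         nodule_mean_hu = -50,
                         background_mean_hu = -850,
                         texture_amplitude_hu = 40,
                         texture_correlation_mm = 2.5,
                         field_of_view_mm = c(36, 36, 36),
                         in_plane_spacing_mm = 0.7,
                         seed = 1L) {
  stopifnot(length(nodule_center_mm) == 3, length(semi_axes_mm) == 3,
            length(field_of_view_mm) == 3)
  if (any(semi_axes_mm < 2 - 1e-9) || any(semi_axes_mm > 12.5 + 1e-9))
    stop("semi_axes_mm must each lie in [2, 12.5]")
  if (any(field_of_view_mm <= 0) || in_plane_spacing_mm <= 0 ||
      texture_correlation_mm <= 0)
    stop("all lengths must be positive")
  if (texture_amplitude_hu < 0) stop("texture_amplitude_hu must be >= 0")
  if (nodule_mean_hu <= background_mean_hu)
    stop("nodule_mean_hu must exceed background_mean_hu")
  lo <- nodule_center_mm - semi_axes_mm
  hi <- nodule_center_mm + semi_axes_mm
  if (any(lo < 0) || any(hi > field_of_view_mm))
    stop("nodule extends outside the field of view: bounding box [",
         paste(sprintf("%.2f", lo), collapse = ", "), "] to [",
         paste(sprintf("%.2f", hi), collapse = ", "), "] vs FOV ",
         paste(field_of_view_mm, collapse = " x "), " mm")
  structure(list(nodule_center_mm = as.numeric(nodule_center_mm),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 nodule_mean_hu = nodule_mean_hu,
                 background_mean_hu = background_mean_hu,
                 texture_amplitude_hu = texture_amplitude_hu,
                 texture_correlation_mm = texture_correlation_mm,
                 field_of_view_mm = as.numeric(field_of_view_mm),
                 in_plane_spacing_mm = in_plane_spacing_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate an expression with a temporary RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic sub-seed derivation
#'
#' Chained Lehmer hash (multiplicative congruential step, modulus 2^31 - 1,
#' multiplier 48271) over a sequence of integers. Exact in double
#' arithmetic, stable across platforms, and always below 2^31; used to give
#' every (nodule, condition) rendering its own reproducible noise seed.
#'
#' @param ... integers to fold into the seed (e.g. master seed, nodule id,
#'   condition index).
#' @return a single integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(...) {
  m <- 2147483647
  a <- 48271
  h <- 17
  for (v in c(...)) {
    h <- (a * h + (as.numeric(v) %% m)) %% m
    h <- (a * h) %% m
  }
  as.integer(if (h == 0) 1 else h)
}

# Band-limited Gaussian random texture field on a fine lattice around the
# nodule, trilinearly interpolated at query points. Frozen by spec$seed.
.texture_field <- function(spec) {
  h <- spec$texture_correlation_mm / 2      # lattice step (band limit)
  sigma_cells <- spec$texture_correlation_mm / h
  margin <- 3 * spec$texture_correlation_mm
  lo <- spec$nodule_center_mm - spec$semi_axes_mm - margin
  n <- ceiling((2 * (spec$semi_axes_mm + margin)) / h) + 1L
  w_r <- ceiling(3 * sigma_cells)
  w <- exp(-0.5 * ((-w_r:w_r) / sigma_cells)^2)
  w <- w / sum(w)
  white <- .with_seed(spec$seed,
                      array(stats::rnorm(prod(n)), dim = n))
  smooth1 <- function(arr, dim_i) {
    nd <- dim(arr)[dim_i]
    K <- matrix(0, nd, nd)
    for (o in -w_r:w_r) {
      idx <- seq_len(nd)
      j <- idx + o
      ok <- j >= 1 & j <= nd
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + w[o + w_r + 1]
    }
    perm <- c(dim_i, setdiff(1:3, dim_i))
    m <- matrix(aperm(arr, perm), nrow = nd)   # nd x rest
    out <- array(K %*% m, dim = dim(arr)[perm])
    aperm(out, order(perm))
  }
  f <- white
  for (d in 1:3) f <- smooth1(f, d)
  # unit-SD normalization from the theoretical SD of separably smoothed
  # white noise (interior cells): prod_d sqrt(sum(w^2))
  f <- f / (sqrt(sum(w^2))^3)
  list(origin = lo, h = h, n = n, values = f)
}

# Trilinear interpolation of the texture lattice at points (N x 3 matrix).
.interp_texture <- function(tex, pts) {
  u <- sweep(pts, 2, tex$origin) / tex$h    # lattice coordinates, 0-based
  i0 <- floor(u)
  fr <- u - i0
  i0 <- i0 + 1                               # 1-based lower cell corner
  for (d in 1:3) {
    i0[, d] <- pmin(pmax(i0[, d], 1), tex$n[d] - 1)
  }
  fr <- pmin(pmax(fr, 0), 1)
  v <- numeric(nrow(pts))
  dims <- tex$n
  at <- function(ix, iy, iz)
    tex$values[cbind(ix, iy, iz)]
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wgt <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
           (if (cy) fr[, 2] else 1 - fr[, 2]) *
           (if (cz) fr[, 3] else 1 - fr[, 3])
    v <- v + wgt * at(i0[, 1] + cx, i0[, 2] + cy, i0[, 3] + cz)
  }
  v
}

#' Generate a continuous nodule phantom
#'
#' Returns a handle mapping any 3-D point (mm) to noiseless HU: background
#' attenuation outside the nodule ellipsoid; nodule mean plus the frozen
#' internal texture inside it. Deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ct_phantom`; call it via `phantom$fun(points)`
#'   where `points` is an N x 3 matrix of mm coordinates.
#' @examples
#' ph <- generate_phantom(phantom_spec(texture_amplitude_hu = 0))
#' ph$fun(matrix(c(18, 18, 18), 1))  # nodule mean, -50
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tex <- if (spec$texture_amplitude_hu > 0) .texture_field(spec) else NULL
  ctr <- spec$nodule_center_mm
  ax <- spec$semi_axes_mm
  delta <- spec$nodule_mean_hu - spec$background_mean_hu
  fun <- function(pts) {
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
    r2 <- ((pts[, 1] - ctr[1]) / ax[1])^2 +
          ((pts[, 2] - ctr[2]) / ax[2])^2 +
          ((pts[, 3] - ctr[3]) / ax[3])^2
    inside <- r2 <= 1
    v <- rep(spec$background_mean_hu, nrow(pts))
    if (any(inside)) {
      add <- delta
      if (!is.null(tex))
        add <- delta + spec$texture_amplitude_hu *
          .interp_texture(tex, pts[inside, , drop = FALSE])
      v[inside] <- v[inside] + add
    }
    v
  }
  structure(list(fun = fun, spec = spec, cache = new.env(parent = emptyenv())),
            class = "ct_phantom")
}

# Rendering-grid geometry shared by volumes and masks. Slice grids at every
# thickness share the inferior field-of-view edge (z = 0) as origin.
.grid_geometry <- function(spec, thickness_mm) {
  sp <- spec$in_plane_spacing_mm
  nx <- as.integer(floor(spec$field_of_view_mm[1] / sp + 1e-9))
  ny <- as.integer(floor(spec$field_of_view_mm[2] / sp + 1e-9))
  nz <- as.integer(floor(spec$field_of_view_mm[3] / thickness_mm + 1e-9))
  list(nx = nx, ny = ny, nz = nz,
       xc = (seq_len(nx) - 0.5) * sp,
       yc = (seq_len(ny) - 0.5) * sp,
       zc = (seq_len(nz) - 0.5) * thickness_mm,
       spacing = c(sp, sp, thickness_mm))
}

# Number of equispaced sub-planes averaged per slab (converged for smooth
# phantoms; kept fixed so cost does not grow with thickness).
.N_SUBPLANES <- 8L

# Noiseless slab-averaged phantom stack for one thickness (pre-blur).
# Cached in the phantom handle: the same stack serves every kernel and dose.
.render_stack <- function(phantom, thickness_mm) {
  key <- sprintf("t%g", thickness_mm)
  if (!is.null(phantom$cache[[key]])) return(phantom$cache[[key]])
  spec <- phantom$spec
  g <- .grid_geometry(spec, thickness_mm)
  k <- .N_SUBPLANES
  sub_z <- as.vector(vapply(seq_len(g$nz), function(i) {
    (i - 1) * thickness_mm + (seq_len(k) - 0.5) * thickness_mm / k
  }, numeric(k)))
  pts <- cbind(rep(g$xc, times = g$ny * length(sub_z)),
               rep(rep(g$yc, each = g$nx), times = length(sub_z)),
               rep(sub_z, each = g$nx * g$ny))
  vals <- phantom$fun(pts)
  planes <- array(vals, dim = c(g$nx, g$ny, k, g$nz))
  stack <- array(0, dim = c(g$nx, g$ny, g$nz))
  for (i in seq_len(g$nz))
    stack[, , i] <- rowMeans(planes[, , , i, drop = FALSE], dims = 2)
  phantom$cache[[key]] <- stack
  stack
}

# In-plane separable Gaussian blur matrix (rows renormalized at edges).
.blur_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  w <- exp(-0.5 * ((-r:r) / sigma_px)^2)
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- w[o + r + 1]
  }
  K / rowSums(K)
}

#' Render a phantom under a reconstruction condition
#'
#' The rendering chain: (1) the continuous phantom is averaged over
#' equispaced sub-planes spanning each slab of the requested thickness
#' (partial-volume averaging; slabs tile the field of view from its inferior
#' edge); (2) the slab image is blurred in-plane with the kernel's Gaussian
#' sigma; (3) white Gaussian noise is added with SD
#' `base_noise_sd_hu * noise_gain(kernel) * dose^(-1/2) * thickness^(-1/2)`.
#'
#' @param phantom a [generate_phantom()] handle.
#' @param condition one-row data.frame or list with `dose_fraction`,
#'   `kernel`, `thickness_mm`.
#' @param model a [degradation_model()].
#' @param noise_seed integer seed for the noise realization.
#' @return an [image_volume()] with spacing metadata and the condition
#'   attached.
#' @export
render_condition <- function(phantom, condition, model = degradation_model(),
                             noise_seed = 1L) {
  stopifnot(inherits(phantom, "ct_phantom"))
  th <- condition$thickness_mm
  if (!th %in% .CT_THICKNESSES)
    stop("thickness ", th, " mm is not in the protocol grid")
  if (!condition$dose_fraction %in% .CT_DOSES)
    stop("dose fraction ", condition$dose_fraction,
         " is not in the protocol grid")
  krow <- .kernel_row(model, condition$kernel)
  spec <- phantom$spec
  g <- .grid_geometry(spec, th)
  stack <- .render_stack(phantom, th)
  sigma_px <- krow$blur_sigma_mm / spec$in_plane_spacing_mm
  Kx <- .blur_matrix(g$nx, sigma_px)
  Ky <- .blur_matrix(g$ny, sigma_px)
  out <- array(0, dim = dim(stack))
  for (i in seq_len(g$nz))
    out[, , i] <- Kx %*% stack[, , i] %*% t(Ky)
  sd <- noise_sd(model, condition$dose_fraction, condition$kernel, th)
  if (sd > 0)
    out <- out + .with_seed(noise_seed,
                            array(stats::rnorm(length(out), sd = sd),
                                  dim = dim(out)))
  image_volume(out, spacing_mm = g$spacing, origin_mm = c(0, 0, 0),
               condition = list(dose_fraction = condition$dose_fraction,
                                kernel = condition$kernel,
                                thickness_mm = th))
}

#' Reference ROI mask for one thickness
#'
#' The per-thickness reference mask: a voxel of the rendering grid at that
#' thickness is inside the mask iff its center lies within the analytic
#' nodule ellipsoid. The same mask serves all 40 dose/kernel combinations at
#' that thickness, so dose and kernel never affect volumetry by
#' construction.
#'
#' @param spec a [phantom_spec()].
#' @param thickness_mm slice thickness (grid member).
#' @param nodule_id optional identifier carried on the mask.
#' @return an [roi_mask()]; if no voxel center falls inside the ellipsoid
#'   the mask is returned empty with `empty = TRUE` and a warning.
#' @export
reference_mask <- function(spec, thickness_mm, nodule_id = NA_character_) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!thickness_mm %in% .CT_THICKNESSES)
    stop("thickness ", thickness_mm, " mm is not in the protocol grid")
  g <- .grid_geometry(spec, thickness_mm)
  ctr <- spec$nodule_center_mm
  ax <- spec$semi_axes_mm
  dx2 <- ((g$xc - ctr[1]) / ax[1])^2
  dy2 <- ((g$yc - ctr[2]) / ax[2])^2
  dz2 <- ((g$zc - ctr[3]) / ax[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  roi_mask(m, spacing_mm = g$spacing, origin_mm = c(0, 0, 0),
           nodule_id = nodule_id,
           allow_empty = TRUE)
}

#' Simulate a cohort of nodules across a condition grid
#'
#' Draws `n_nodules` phantom specifications (geometry and texture frozen by
#' `master_seed`), and returns them with their per-thickness reference masks
#' and a renderer. Noise seeds are derived deterministically from
#' (master_seed, nodule, condition index) so the whole cohort is
#' reproducible bit-for-bit.
#'
#' @param n_nodules number of nodules (>= 1).
#' @param master_seed integer master seed.
#' @param model a [degradation_model()].
#' @param grid condition grid (default the full 320-condition grid); pass a
#'   subset from [condition_grid()] for desk-scale runs.
#' @param radius_range range of the mean nodule radius in mm
#'   (default c(2.5, 10), i.e. 5-20 mm diameter solid nodules).
#' @param shape "ellipsoid" (mild anisotropy, default) or "sphere".
#' @param keep_volumes if TRUE, render and store every (nodule, condition)
#'   volume in memory (only sensible for small grids); if FALSE (default)
#'   volumes are rendered on demand via the returned `render` function.
#' @param texture_amplitude_hu,texture_correlation_mm texture parameters
#'   passed to [phantom_spec()].
#' @return object of class `ct_cohort`: list with `specs`, `masks`
#'   (nodule x thickness), `grid`, `model`, `master_seed`, `render(nodule,
#'   condition_index)` and, when requested, `volumes`.
#' @export
simulate_cohort <- function(n_nodules, master_seed,
                            model = degradation_model(),
                            grid = condition_grid(),
                            radius_range = c(2.5, 10),
                            shape = c("ellipsoid", "sphere"),
                            keep_volumes = FALSE,
                            texture_amplitude_hu = 40,
                            texture_correlation_mm = 2.5) {
  stopifnot(n_nodules >= 1)
  shape <- match.arg(shape)
  fov <- c(36, 36, 36)
  specs <- vector("list", n_nodules)
  for (i in seq_len(n_nodules)) {
    geom_seed <- derive_seed(master_seed, 1L, i)
    g <- .with_seed(geom_seed, {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      fac <- if (shape == "sphere") rep(1, 3) else stats::runif(3, 0.85, 1.15)
      ax <- pmin(pmax(r * fac, 2), 12.5)
      ctr <- fov / 2 + stats::runif(3, -1.5, 1.5)
      list(ax = ax, ctr = ctr)
    })
    # keep the nodule inside the FOV
    g$ctr <- pmin(pmax(g$ctr, g$ax + 0.5), fov - g$ax - 0.5)
    specs[[i]] <- phantom_spec(
      nodule_center_mm = g$ctr, semi_axes_mm = g$ax,
      texture_amplitude_hu = texture_amplitude_hu,
      texture_correlation_mm = texture_correlation_mm,
      field_of_view_mm = fov,
      seed = derive_seed(master_seed, 2L, i))
  }
  ids <- sprintf("nodule%02d", seq_len(n_nodules))
  thicknesses <- sort(unique(grid$thickness_mm))
  masks <- lapply(seq_len(n_nodules), function(i) {
    ms <- lapply(thicknesses, function(th)
      reference_mask(specs[[i]], th, nodule_id = ids[i]))
    names(ms) <- sprintf("%g", thicknesses)
    ms
  })
  names(masks) <- ids
  phantoms <- new.env(parent = emptyenv())
  get_phantom <- function(i) {
    key <- as.character(i)
    if (is.null(phantoms[[key]]))
      phantoms[[key]] <- generate_phantom(specs[[i]])
    phantoms[[key]]
  }
  render <- function(nodule, condition_index) {
    row <- grid[grid$index == condition_index, ]
    if (nrow(row) != 1) stop("condition index ", condition_index,
                             " not in this cohort's grid")
    render_condition(get_phantom(nodule), row, model,
                     noise_seed = derive_seed(master_seed, 3L, nodule,
                                              condition_index))
  }
  cohort <- structure(list(specs = specs, nodule_ids = ids, masks = masks,
                           grid = grid, model = model,
                           master_seed = master_seed, render = render),
                      class = "ct_cohort")
  if (keep_volumes) {
    cohort$volumes <- lapply(seq_len(n_nodules), function(i)
      lapply(seq_len(nrow(grid)), function(ci) render(i, grid$index[ci])))
    names(cohort$volumes) <- ids
  }
  cohort
}
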