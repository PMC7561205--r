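cond <- function(d, k, t) list(dose_fraction = d, kernel = k,
                               thickness_mm = t)

test_that("phantom field hits its nominal values and is deterministic", {
  sp <- phantom_spec(texture_amplitude_hu = 0)
  ph <- generate_phantom(sp)
  ctr <- matrix(sp$nodule_center_mm, 1)
  expect_identical(ph$fun(ctr), -50)
  # >= 3 semi-axes from center: background exactly
  far <- matrix(sp$nodule_center_mm - c(sp$nodule_center_mm[1] - 1, 0, 0), 1)
  expect_identical(ph$fun(far), -850)
  sp2 <- phantom_spec(seed = 7)
  set.seed(99)
  pts <- matrix(runif(300, 6, 30), ncol = 3)
  v1 <- generate_phantom(sp2)$fun(pts)
  v2 <- generate_phantom(sp2)$fun(pts)
  expect_identical(v1, v2)
  v3 <- generate_phantom(phantom_spec(seed = 8))$fun(pts)
  expect_false(identical(v1, v3))
  # bounded field
  expect_true(all(is.finite(v1)))
})

test_that("a nodule outside the field of view is rejected", {
  expect_error(phantom_spec(nodule_center_mm = c(3, 18, 18),
                            semi_axes_mm = c(8, 8, 8)),
               "outside the field of view")
  expect_error(phantom_spec(nodule_mean_hu = -900), "must exceed")
  expect_error(phantom_spec(semi_axes_mm = c(1, 8, 8)), "semi_axes")
})

test_that("degradation model enforces sharpness monotonicity and IR factor", {
  m <- degradation_model()
  gains <- sapply(c("B31f", "B40f", "B50f", "B60f", "B70f"),
                  function(k) noise_gain(m, k))
  expect_true(all(diff(gains) > 0))
  gains_i <- sapply(c("I26f", "I31f", "I40f", "I50f", "I70f"),
                    function(k) noise_gain(m, k))
  expect_true(all(diff(gains_i) > 0))
  expect_equal(noise_gain(m, "I50f") / noise_gain(m, "B50f"), 0.7)
  expect_error(degradation_model(ir_noise_factor = 0), "ir_noise_factor")
  expect_error(degradation_model(ir_noise_factor = 1.2), "ir_noise_factor")
  expect_error(noise_sd(m, 1, "X99x", 1), "X99x")
})

test_that("background noise SD scales as dose^(-1/2), thickness^(-1/2), gain", {
  ph <- generate_phantom(phantom_spec())
  model <- degradation_model()
  bg <- function(v) v$voxels[1:6, , ]   # region far from the nodule
  v100 <- render_condition(ph, cond(1, "B50f", 1), model, noise_seed = 11)
  v25 <- render_condition(ph, cond(0.25, "B50f", 1), model, noise_seed = 12)
  expect_gt(length(bg(v100)), 1e4)
  expect_equal(sd(bg(v25)) / sd(bg(v100)), 2, tolerance = 0.05)
  vI <- render_condition(ph, cond(1, "I50f", 1), model, noise_seed = 13)
  expect_equal(sd(bg(vI)) / sd(bg(v100)), 0.7, tolerance = 0.05)
  v4 <- render_condition(ph, cond(1, "B50f", 4), model, noise_seed = 14)
  expect_equal(sd(bg(v4)) / sd(bg(v100)), 0.5, tolerance = 0.05)
  v70 <- render_condition(ph, cond(1, "B70f", 1), model, noise_seed = 15)
  expect_equal(sd(bg(v70)) / sd(bg(v100)), 2, tolerance = 0.05)
})

test_that("zero-noise rendering is deterministic and thickness-consistent", {
  ph <- generate_phantom(phantom_spec())
  m0 <- degradation_model(base_noise_sd_hu = 0)
  a <- render_condition(ph, cond(1, "B50f", 1), m0, noise_seed = 1)
  b <- render_condition(ph, cond(1, "B50f", 1), m0, noise_seed = 2)
  expect_identical(a$voxels, b$voxels)
  expect_equal(a$spacing_mm, c(0.7, 0.7, 1.0))
  # averaging two adjacent 1 mm slabs ~ the aligned 2 mm slab
  z2 <- render_condition(ph, cond(1, "B50f", 2), m0, noise_seed = 1)
  nz2 <- dim(z2$voxels)[3]
  avg <- (a$voxels[, , 2 * seq_len(nz2) - 1] + a$voxels[, , 2 * seq_len(nz2)]) / 2
  d <- abs(avg - z2$voxels)
  expect_lt(mean(d), 5)          # sub-plane quadrature error at the rim
  expect_lt(max(d), 60)
})

test_that("reference masks voxelize the analytic ellipsoid", {
  sp <- phantom_spec(semi_axes_mm = c(5, 5, 5), texture_amplitude_hu = 0)
  m1 <- reference_mask(sp, 1.0)
  expect_equal(mask_volume(m1), 4 / 3 * pi * 5^3, tolerance = 0.1)
  m5 <- reference_mask(sp, 5.0)
  n_slices <- function(m) sum(apply(m$voxels, 3, any))
  expect_lt(n_slices(m5), n_slices(m1))
  # convergence: finer in-plane spacing + thinner slices -> closer volume
  spf <- phantom_spec(semi_axes_mm = c(5, 5, 5), in_plane_spacing_mm = 0.35,
                      texture_amplitude_hu = 0)
  err <- function(m) abs(mask_volume(m) - 4 / 3 * pi * 5^3)
  expect_lt(err(reference_mask(spf, 0.6)), err(reference_mask(sp, 5.0)))
  # a tiny nodule lying between 5 mm slice centers gives an empty mask,
  # flagged rather than fatal
  spt <- phantom_spec(nodule_center_mm = c(18, 18, 20.0),
                      semi_axes_mm = c(2, 2, 2), texture_amplitude_hu = 0)
  expect_warning(me <- reference_mask(spt, 5.0), "empty ROI")
  expect_true(me$empty)
})

test_that("sub-seed derivation is stable, bounded and collision-spread", {
  s1 <- derive_seed(1, 3, 2, 100)
  expect_identical(s1, derive_seed(1, 3, 2, 100))
  expect_true(s1 > 0 && s1 < 2^31)
  seeds <- sapply(0:319, function(ci) derive_seed(1, 3, 1, ci))
  expect_equal(length(unique(seeds)), 320L)
  expect_false(derive_seed(2, 3, 1, 0) == derive_seed(1, 3, 1, 0))
})

test_that("simulate_cohort is reproducible and counts line up", {
  g <- condition_grid(doses = 1, kernels = "B50f", thicknesses = c(1, 3))
  co <- simulate_cohort(3, master_seed = 5, grid = g, keep_volumes = TRUE)
  expect_length(co$volumes, 3L)
  expect_length(co$volumes[[1]], nrow(g))
  expect_length(co$masks[[1]], 2L)
  co2 <- simulate_cohort(3, master_seed = 5, grid = g, keep_volumes = TRUE)
  expect_identical(co$volumes[[2]][[1]]$voxels, co2$volumes[[2]][[1]]$voxels)
  co3 <- simulate_cohort(3, master_seed = 6, grid = g, keep_volumes = TRUE)
  expect_false(identical(co$volumes[[2]][[1]]$voxels,
                         co3$volumes[[2]][[1]]$voxels))
})
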