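---
title: "Methods: simulating and mapping radiomic compatibility across CT reconstruction conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping radiomic compatibility across CT reconstruction conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

A quantitative imaging pipeline measures a lung nodule's volume and a panel
of texture features from a segmented CT volume. Any of three reconstruction
choices — radiation dose, convolution kernel, slice thickness — changes the
voxel data and therefore the measurements. `ctcompat` treats this as a
statistical compatibility question: for every pair of reconstruction
conditions, would the measured features be statistically indistinguishable?
The package answers it on simulated cohorts (no patient data required) and
on user-supplied NIfTI volumes with per-thickness reference ROI masks.
DICOM series input is out of scope; NIfTI is the supported on-disk format.

## Study design

The condition grid crosses 4 dose fractions (12.5, 25, 50, 100%), 10
kernels (a filtered-back-projection family B31f–B70f and an iterative
family I26f–I70f) and 8 thicknesses (0.6–5 mm): 320 conditions, each with a
stable index. Segmentation follows the reference-ROI design: one mask per
(nodule, thickness), drawn from the 100%-dose/B50f condition, shared by all
40 dose × kernel combinations at that thickness. Two consequences are
deliberate and documented rather than incidental:

* volumetry depends on thickness only — dose and kernel cannot move a
  volume because the mask never changes with them;
* slice qualification for feature extraction is identical across the 40
  conditions of a thickness, so sample sizes in the t statistic are matched
  within thickness.

## The degradation model

The simulator is an image-domain surrogate for the acquisition and
reconstruction chain, built from three effects that the downstream
statistics must be able to detect:

1. **Partial volume.** Each output slab is the mean of the continuous
   phantom over `k = 8` equispaced sub-planes spanning the slab. Eight
   planes keep the cost independent of thickness and are converged for the
   smooth phantom interior; the residual midpoint-rule error is confined to
   the ellipsoid rim (the thickness-consistency test tolerates a mean
   discrepancy of 5 HU between one 2 mm slab and the average of its two
   aligned 1 mm slabs).
2. **Kernel blur and noise gain.** Each kernel has an in-plane Gaussian
   blur sigma (mm) and a noise gain. Within each family, sharpness
   increases with the kernel number: sigma strictly decreases
   (1.2 → 0.35 mm across the B family) and gain strictly increases
   (0.7 → 2.0). The iterative family reuses the blur of the matching B
   kernel and multiplies its gain by `ir_noise_factor = 0.7` — iterative
   reconstruction suppresses noise at matched sharpness. I26f, smoother
   than anything in the B family, gets blur 1.4 mm and base gain 0.6;
   the IR factor applies to it like to the rest of its family, keeping
   within-family monotonicity intact.
3. **Quantum noise.** White Gaussian noise in HU with
   `SD = base_noise_sd_hu × gain(kernel) × dose^(−1/2) × thickness^(−1/2)`,
   `base_noise_sd_hu = 12` at the 100%-dose/B50f/1 mm anchor — a typical
   parenchymal noise level. The dose exponent is photon statistics; the
   thickness exponent is photon averaging across the slab. Noise is added
   after blur and is spatially uncorrelated: the model deliberately omits
   noise texture (the kernel-dependent noise power spectrum of real
   reconstructions), which is the main feature of real data the simulator
   does not emulate. Passing tests therefore demonstrate that the
   statistics respond correctly to noise magnitude, resolution and
   partial-volume effects — not that the phantom reproduces scanner noise
   correlation structure.

The phantom itself is an ellipsoid (semi-axes 2–12.5 mm, −50 HU) in a
−850 HU background with a band-limited Gaussian random texture field inside
(amplitude 40 HU, correlation length 2.5 mm, generated on a lattice of half
the correlation length and tri-linearly interpolated). Texture is anatomy:
it is frozen per nodule by its own seed, while every rendering draws fresh
noise. Sub-seeds derive from (master seed, purpose tag, nodule, condition
index) through a chained Lehmer hash — exact in double arithmetic, stable
across platforms, always below 2^31.

## Feature extraction choices

The compatibility t-test needs a mean, an SD and a sample size per
(nodule, condition, feature). A single 3-D feature value has no
within-nodule spread, so the package uses per-axial-slice values as the
sample unit — the natural reading of a per-slice ROI stack. This is an
interpretive choice and is stated as such.

* **Quantization**: `Ng = 32` levels over a fixed (−1000, 400) HU window,
  identical across conditions — cross-condition comparability requires a
  shared level map. `level = 1 + floor(Ng · clip(u, 0, 1−1e−12))` with `u`
  the window-relative position; values at the window edges land in the
  first/last bin.
* **GLCM**: distance 1, four in-plane directions, symmetric accumulation,
  features averaged over directions (the classic Haralick protocol). Pairs
  are counted only when both pixels are in the ROI. The inverse difference
  moment uses `(i−j)²`; the second information measure of correlation uses
  the square-root form.
* **RLM**: the same four directions, averaged; runs break at the ROI
  boundary so no out-of-nodule pixels leak into run statistics. Run
  percentage divides by the slice's ROI pixel count.
* **NGLDM**: Chebyshev radius `d = 1`, tolerance `a = 0`; the small-number
  emphasis sums over dependence counts `s ≥ 1` only, since `1/s²` is
  undefined at `s = 0` (the `s = 0` column still contributes to the
  normalizing total).
* **NGTDM**: 8-neighbor ring; a pixel is valid if it has at least one
  in-ROI neighbor, and its neighborhood mean uses the available neighbors.
  Texture strength is the Amadasun–King ratio. The coarseness denominator
  is guarded at 1e−12, so a perfectly flat region reports the 1e12 cap
  rather than infinity.
* **Histogram features** are computed on raw HU and are therefore invariant
  to quantization settings. Their moment normalizations mix `1/N` and
  `1/(N−1)` factors exactly as defined in `histogram_features()`.
* **Imputation**: any feature undefined on a slice (flat region, no valid
  co-occurrence pair, no pixel with a neighbor) is written as 0 and the
  slice's flag column names it, so downstream sample sets are complete and
  every imputation is auditable in `features.csv`.
* **Qualification**: a slice needs `min_pixels = 10` ROI pixels (below
  that, matrix statistics are mostly degenerate); a (nodule, condition)
  needs `min_slices = 3` (the t-test needs n ≥ 2; one extra for stability).
  Nodules failing this are excluded as *non-evaluable* — see below.

## Statistical conventions

* The t statistic is computed from summary statistics; p-values use the
  standard normal CDF, because the 1.96 threshold is paired with P < 0.05
  regardless of degrees of freedom. This is a faithful implementation of
  the criterion as stated, not a Student-t approximation.
* Zero-variance conventions: equal means with zero pooled SE → t = 0
  (compatible); unequal means with zero pooled SE → t = ∞ (incompatible).
* No multiple-testing correction is applied anywhere.
* The compatibility-ratio denominator is `28 × n_patients` when every cell
  is evaluable; when a nodule is excluded at a condition the denominator
  shrinks to the evaluable (feature, patient) cells. Scoring an exclusion
  as "incompatible" would conflate data sufficiency with incompatibility;
  the adjustment is this package's own policy and exclusions are logged in
  `exclusions.csv`.
* The map is stored as the full symmetric matrix; the comparison census
  `n_conditions² × 28 × n_patients` counts ordered pairs including the
  diagonal.
* Display ordering of the map (thickness 5 → 0.6 mm; kernels I26f, I31f,
  B31f, I40f, B40f, I50f, B50f, I70f, B60f, B70f; dose 100 → 12.5%) is
  fixed report metadata; the matrix itself is order-independent.

## Degenerate inputs and numerical guards

Empty reference masks (a tiny nodule falling between 5 mm slice centers)
are allowed but flagged, and exclude the nodule from volumetry with a
message. Volume normalization requires all thicknesses present and
positive. Masks must share the exact voxel grid of their volume; I/O never
resamples. CSV output serializes doubles at 17 significant digits so
re-runs are byte-comparable; every table carries a hash of the full study
configuration as a comment line.

## Cohort defaults and test problem sizes

The simulated cohort draws mean nodule radii uniformly from 2.5–10 mm
(5–20 mm diameter solid nodules, with mild per-axis anisotropy unless
spheres are requested) centered in a 36 mm field of view at 0.7 mm in-plane
spacing. The test suite exercises: oracle equivalence of all matrix-family
features against brute-force enumerations on 100+ random ≤8×8 slices at
1e−10 relative tolerance; noise-scaling ratios on ≥10⁴ background voxels at
5% tolerance; the qualitative reproducibility properties (volumetric spread
non-decreasing with thickness above 2 mm; dose-change compatibility higher
at 5 mm/I26f than at 0.6 mm/B70f) on 20-nodule cohorts over three master
seeds with a reduced 2 × 4 × 4 grid; and byte-identical re-runs of the
small-grid pipeline. These sizes were chosen to make each property
detectable with margin on a single CPU; the full 320-condition grid is
exercised with a 3-nodule cohort in `scripts/acceptance.R`.

## Known limitations

* The degradation model is not a reconstruction: no sinogram-domain dose
  insertion, no scanner MTF/NPS matching, no noise correlation. Absolute
  compatibility percentages from simulations should not be read as clinical
  estimates; the reliable outputs are orderings and structural properties.
* Ground-glass components are not modeled — nodules are solid.
* Per-slice sampling makes thin-slice conditions carry larger sample sizes
  (more slices), which sharpens their t-tests; this mirrors the underlying
  design (thin slices genuinely carry more within-nodule samples) but
  couples thickness to statistical power.
* Feature-extraction parameters that published pipelines leave unspecified
  (Ng, GLCM distance, NGLDM d and a, NGTDM neighborhood) are set to the
  field's customary defaults and are configurable; results depend on them.
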