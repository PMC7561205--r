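# ctcompat

Reproducibility analysis of quantitative lung-nodule imaging across CT
acquisition and reconstruction conditions.

Radiomic features of a lung nodule — its volume, density histogram and
texture statistics — are only useful for longitudinal or multi-site studies
if they survive changes in how the CT examination was acquired and
reconstructed. `ctcompat` quantifies that: it simulates solid nodules imaged
under a grid of **4 radiation doses × 10 reconstruction kernels × 8 slice
thicknesses** (320 conditions), extracts 28 per-slice texture features per
condition, and maps which condition pairs leave volumetry and radiomics
statistically unchanged. The same statistics run on user-supplied NIfTI
volumes and ROI masks laid out with per-thickness reference ROIs.

It is aimed at imaging scientists studying radiomic feature stability and at
anyone designing scan protocols who needs to know which parameter changes
are "compatible" with an existing quantitative baseline.

## The statistics

**Normalized volume.** Each nodule is segmented once per slice thickness
(on the 100%-dose/B50f reference reconstruction); its volume at thickness
*i* is normalized by the nodule's mean across the 8 thicknesses:

    V_norm,i = V_i / ( (1/8) Σ_k V_k )

so the 8 values of each nodule average exactly 1.

**Compatibility criterion.** Two samples (means m₁, m₂; SDs s₁, s₂; sizes
n₁, n₂) are *compatible* when the two-tailed statistic

    t = |m₁ − m₂| / sqrt(s₁²/n₁ + s₂²/n₂)

is below 1.96 (P < 0.05 on the normal scale). For volumetry the samples are
normalized volumes across nodules; for radiomics they are per-slice feature
values within one nodule.

**Compatibility ratio.** For a pair of reconstruction conditions (R_i, R_j),

    CR(R_i, R_j) = Σ_f Σ_p C(R_i,R_j)(f, p) / (28 × n_patients) × 100

where C is the boolean compatibility of feature *f* for patient *p*. The
320 × 320 matrix of CR values is the compatibility map; its diagonal is
100% by construction. When a nodule is excluded at a condition (too few
qualifying slices) the denominator shrinks to the evaluable cells.

**Features.** 5 histogram features (mean, contrast, SD, skewness,
kurtosis, computed on raw HU), 13 gray-level co-occurrence (Haralick)
features, 5 run-length features, 2 gray-level-dependence features and
3 gray-tone-difference features (coarseness, complexity, strength), all
computed per axial ROI slice on a shared 32-level quantization of the
(−1000, 400) HU window.

**Simulator.** Nodules are ellipsoids (2–12.5 mm semi-axes, −50 HU) with
band-limited internal texture in a −850 HU lung background. A condition is
rendered by averaging the continuous phantom over 8 sub-planes per slab
(partial volume), blurring in-plane with a kernel-specific Gaussian, and
adding white noise with SD ∝ kernel gain × dose^(−1/2) × thickness^(−1/2).
Iterative-reconstruction kernels carry a 0.7× noise factor at matched
sharpness.

## Worked example

A desk-scale study: 3 nodules on a 2 × 2 × 2 condition grid
(doses 50/100%, kernels B31f/B50f, thicknesses 1/3 mm).

```r
library(ctcompat)
cfg <- study_config(n_nodules = 3, master_seed = 1, grid = "small")
run_pipeline(cfg, "demo")   # all stages, incl. figures

read_table("demo/thickness_deviation.csv")
#>   thickness_mm  mean_pct   sd_pct n
#> 1            1  2.137518 4.343224 3
#> 2            3 -2.137518 4.343224 3
```

With only two thicknesses each nodule's normalized volumes are mirror
images around 1: the 1 mm reconstruction measures on average 2.1% above the
nodule's mean volume, the 3 mm one 2.1% below — the partial-volume bias that
grows with slab height.

```r
md <- read_table("demo/compatibility_map.csv")
round(as.matrix(md[, grep("^cr_", names(md))]), 1)
#>      cr_000 cr_001 cr_002 cr_003 cr_004 cr_005 cr_006 cr_007
#> [1,]  100.0   96.4   44.0   38.1   94.6   92.9   78.6   80.4
#> [2,]   96.4  100.0   51.2   46.4   98.2   96.4   85.7   87.5
#> [3,]   44.0   51.2  100.0   90.5   53.6   55.4   91.1   87.5
#> [4,]   38.1   46.4   90.5  100.0   51.8   55.4   94.6   91.1
#> [5,]   94.6   98.2   53.6   51.8  100.0  100.0   94.6   98.2
#> [6,]   92.9   96.4   55.4   55.4  100.0  100.0   94.6   98.2
#> [7,]   78.6   85.7   91.1   94.6   94.6   94.6  100.0  100.0
#> [8,]   80.4   87.5   87.5   91.1   98.2   98.2  100.0  100.0
```

Each entry is the percentage of the 28 × 3 (feature, nodule) cells that are
statistically unchanged between two conditions. The diagonal is 100%; the
lowest entries (38–44%) pair a 1 mm/B31f reconstruction against 3 mm/B50f —
two parameters changed at once. Rows 1–4 are 1 mm conditions, rows 5–8 are
3 mm; within-thickness blocks stay above 90%.

`run_pipeline` also writes `features.csv` (per-slice feature table),
`feature_robustness.csv` (per-feature compatibility under dose-only,
kernel-only and thickness-only changes), pairwise kernel/thickness/dose
tables, and heatmap/trend figures under the output directory.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/ctcompat-run.R`:

```sh
Rscript inst/scripts/ctcompat-run.R all --out study --seed 1 --n-nodules 5 --grid small
```
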