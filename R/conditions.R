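# Canonical factor levels of the acquisition/reconstruction grid.
.CT_DOSES <- c(0.125, 0.25, 0.5, 1.0)
.CT_KERNELS <- c("B31f", "B40f", "B50f", "B60f", "B70f",
                 "I26f", "I31f", "I40f", "I50f", "I70f")
.CT_THICKNESSES <- c(0.6, 0.75, 1.0, 1.5, 2.0, 3.0, 4.0, 5.0)

# Display orders used by the compatibility-map report (sorted by observed
# total compatibility in the source protocol; kept as fixed metadata here).
.SORT_THICKNESS <- c(5.0, 4.0, 3.0, 2.0, 1.5, 1.0, 0.75, 0.6)
.SORT_KERNEL <- c("I26f", "I31f", "B31f", "I40f", "B40f",
                  "I50f", "B50f", "I70f", "B60f", "B70f")
.SORT_DOSE <- c(1.0, 0.5, 0.25, 0.125)

#' Enumerate the reconstruction-condition grid
#'
#' A reconstruction condition is one cell of the dose x kernel x thickness
#' grid under which a CT examination is reconstructed. The full protocol grid
#' has 4 dose fractions (12.5, 25, 50, 100 percent of protocol dose),
#' 10 kernels (a filtered-back-projection family B31f..B70f and an iterative
#' family I26f..I70f) and 8 slice thicknesses (0.6 to 5 mm), i.e. 320
#' conditions. Each condition carries a stable integer index, assigned in
#' row order of the returned frame: thickness varies slowest, then kernel,
#' then dose.
#'
#' @param doses numeric vector of dose fractions (subset of the protocol
#'   doses 0.125, 0.25, 0.5, 1).
#' @param kernels character vector of kernel labels (subset of the 10
#'   protocol kernels).
#' @param thicknesses numeric vector of slice thicknesses in mm (subset of
#'   the 8 protocol thicknesses).
#' @return A data.frame with columns `index` (0-based, stable within the
#'   requested grid), `dose_fraction`, `kernel`, `thickness_mm`, and
#'   `is_reference` (TRUE for the 100%-dose/B50f condition of each
#'   thickness, from which reference ROIs are drawn).
#' @examples
#' g <- condition_grid()
#' nrow(g)            # 320
#' sum(g$is_reference) # 8, one per thickness
#' @export
condition_grid <- function(doses = .CT_DOSES,
                           kernels = .CT_KERNELS,
                           thicknesses = .CT_THICKNESSES) {
  if (!all(doses %in% .CT_DOSES))
    stop("unknown dose fraction(s): ",
         paste(setdiff(doses, .CT_DOSES), collapse = ", "))
  if (!all(kernels %in% .CT_KERNELS))
    stop("unknown kernel label(s): ",
         paste(setdiff(kernels, .CT_KERNELS), collapse = ", "))
  if (!all(thicknesses %in% .CT_THICKNESSES))
    stop("unknown slice thickness(es): ",
         paste(setdiff(thicknesses, .CT_THICKNESSES), collapse = ", "))
  g <- expand.grid(dose_fraction = doses, kernel = kernels,
                   thickness_mm = thicknesses,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(match(g$thickness_mm, .CT_THICKNESSES),
               match(g$kernel, .CT_KERNELS),
               match(g$dose_fraction, .CT_DOSES)), , drop = FALSE]
  rownames(g) <- NULL
  g$index <- seq_len(nrow(g)) - 1L
  g$is_reference <- g$dose_fraction == 1.0 & g$kernel == "B50f"
  g[, c("index", "dose_fraction", "kernel", "thickness_mm", "is_reference")]
}

#' Reference condition for a slice thickness
#'
#' Reference ROIs are segmented once per thickness on the 100%-dose/B50f
#' reconstruction and then propagated to every dose/kernel combination at
#' that thickness.
#'
#' @param thickness_mm slice thickness in mm (must be a grid member).
#' @return one-row data.frame (dose_fraction, kernel, thickness_mm).
#' @export
reference_condition <- function(thickness_mm) {
  if (!thickness_mm %in% .CT_THICKNESSES)
    stop("thickness ", thickness_mm, " mm is not in the protocol grid")
  data.frame(dose_fraction = 1.0, kernel = "B50f",
             thickness_mm = thickness_mm, stringsAsFactors = FALSE)
}

#' Ordered-pair comparison accounting
#'
#' Total number of (condition, condition, feature, patient) comparisons that
#' a full compatibility map performs, counting both orders of each condition
#' pair and the diagonal: `n_conditions^2 * n_features * n_patients`.
#'
#' @param n_conditions,n_features,n_patients counts (defaults: the full
#'   320-condition grid, 28 features, 23 patients).
#' @return comparison count (numeric, exact).
#' @examples
#' comparison_count()  # 65945600
#' @export
comparison_count <- function(n_conditions = 320L, n_features = 28L,
                             n_patients = 23L) {
  as.numeric(n_conditions)^2 * n_features * n_patients
}

#' Display ordering of conditions for the compatibility map
#'
#' Returns the row ordering of a condition grid under the report's sort:
#' thickness 5 mm down to 0.6 mm, kernels from smoothest-iterative to
#' sharpest-FBP (I26f, I31f, B31f, I40f, B40f, I50f, B50f, I70f, B60f,
#' B70f), dose 100% down to 12.5%.
#'
#' @param grid data.frame from [condition_grid()].
#' @return integer permutation of `seq_len(nrow(grid))`.
#' @export
condition_sort_order <- function(grid) {
  order(match(grid$thickness_mm, .SORT_THICKNESS),
        match(grid$kernel, .SORT_KERNEL),
        match(grid$dose_fraction, .SORT_DOSE))
}

#' Human-readable condition labels
#' @param grid data.frame from [condition_grid()].
#' @return character vector like "5mm/I26f/100%".
#' @export
condition_label <- function(grid) {
  sprintf("%gmm/%s/%g%%", grid$thickness_mm, grid$kernel,
          100 * grid$dose_fraction)
}
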