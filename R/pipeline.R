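# End-to-end study driver: simulate a cohort, extract per-slice features,
# run the volumetric and radiomic compatibility analyses, and write
# diff-able CSV outputs plus figures. Every stage is deterministic given the
# config's master seed; stages are resumable from the CSVs already present
# in the output directory.

#' Study configuration
#'
#' Collects every tunable of a simulation study with documented defaults.
#' The configuration is serialized into the output directory and hashed;
#' each output table carries the hash as a comment line.
#'
#' @param n_nodules cohort size (default 3).
#' @param master_seed integer master seed (default 1).
#' @param grid "full" (320 conditions), "small" (a 2 x 2 x 2 desk-scale
#'   subset), or a list with `doses`, `kernels`, `thicknesses`.
#' @param base_noise_sd_hu,ir_noise_factor degradation-model parameters.
#' @param radius_range,shape,texture_amplitude_hu,texture_correlation_mm
#'   cohort geometry/texture parameters, see [simulate_cohort()].
#' @param Ng,hu_window,min_pixels,min_slices feature-extraction settings,
#'   see [feature_settings()].
#' @return list of class `study_config`.
#' @export
study_config <- function(n_nodules = 3L, master_seed = 1L,
                         grid = "full",
                         base_noise_sd_hu = 12,
                         ir_noise_factor = 0.7,
                         radius_range = c(2.5, 10),
                         shape = "ellipsoid",
                         texture_amplitude_hu = 40,
                         texture_correlation_mm = 2.5,
                         Ng = 32L, hu_window = c(-1000, 400),
                         min_pixels = 10L, min_slices = 3L) {
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("full", "small")),
                   full = list(doses = .CT_DOSES, kernels = .CT_KERNELS,
                               thicknesses = .CT_THICKNESSES),
                   small = list(doses = c(0.5, 1.0),
                                kernels = c("B31f", "B50f"),
                                thicknesses = c(1.0, 3.0)))
  }
  stopifnot(is.list(grid),
            all(c("doses", "kernels", "thicknesses") %in% names(grid)))
  structure(list(n_nodules = as.integer(n_nodules),
                 master_seed = as.integer(master_seed),
                 grid = grid,
                 base_noise_sd_hu = base_noise_sd_hu,
                 ir_noise_factor = ir_noise_factor,
                 radius_range = radius_range, shape = shape,
                 texture_amplitude_hu = texture_amplitude_hu,
                 texture_correlation_mm = texture_correlation_mm,
                 Ng = as.integer(Ng), hu_window = hu_window,
                 min_pixels = as.integer(min_pixels),
                 min_slices = as.integer(min_slices)),
            class = "study_config")
}

# Hash of the canonical config JSON (hex string): the same chained Lehmer
# mix as derive_seed, folded over the JSON bytes.
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", derive_seed(utf8ToInt(as.character(js))))
}

.cfg_grid <- function(config) {
  condition_grid(doses = config$grid$doses, kernels = config$grid$kernels,
                 thicknesses = config$grid$thicknesses)
}

.cfg_cohort <- function(config) {
  simulate_cohort(config$n_nodules, config$master_seed,
                  model = degradation_model(config$base_noise_sd_hu,
                                            ir_noise_factor =
                                              config$ir_noise_factor),
                  grid = .cfg_grid(config),
                  radius_range = config$radius_range,
                  shape = config$shape,
                  texture_amplitude_hu = config$texture_amplitude_hu,
                  texture_correlation_mm = config$texture_correlation_mm)
}

.cfg_settings <- function(config) {
  feature_settings(Ng = config$Ng, hu_window = config$hu_window,
                   min_pixels = config$min_pixels,
                   min_slices = config$min_slices)
}

#' Extract the feature table of a cohort
#'
#' Streams through every (nodule, condition): renders the volume, extracts
#' the per-slice features against the per-thickness reference mask, and
#' discards the volume. Returns the long feature table plus the exclusion
#' log.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param settings a [feature_settings()].
#' @return list with `features` (data.frame: nodule_id, condition_index,
#'   slice_index, 28 feature columns, imputed) and `exclusions`
#'   (data.frame: nodule_id, condition_index, reason).
#' @export
cohort_feature_table <- function(cohort, settings = feature_settings()) {
  stopifnot(inherits(cohort, "ct_cohort"))
  grid <- cohort$grid
  rows <- list()
  excl <- list()
  for (i in seq_along(cohort$nodule_ids)) {
    id <- cohort$nodule_ids[i]
    for (ci in seq_len(nrow(grid))) {
      th <- grid$thickness_mm[ci]
      mask <- cohort$masks[[i]][[sprintf("%g", th)]]
      if (mask$empty) {
        excl[[length(excl) + 1L]] <- data.frame(
          nodule_id = id, condition_index = grid$index[ci],
          reason = "empty reference mask", stringsAsFactors = FALSE)
        next
      }
      vol <- cohort$render(i, grid$index[ci])
      fs <- extract_samples(vol, mask, settings, nodule_id = id,
                            condition_index = grid$index[ci])
      if (!fs$evaluable) {
        excl[[length(excl) + 1L]] <- data.frame(
          nodule_id = id, condition_index = grid$index[ci],
          reason = fs$reason, stringsAsFactors = FALSE)
        next
      }
      df <- as.data.frame(fs$features)
      df <- cbind(data.frame(nodule_id = id,
                             condition_index = grid$index[ci],
                             slice_index = fs$slice_index,
                             stringsAsFactors = FALSE),
                  df)
      df$imputed <- fs$imputed
      rows[[length(rows) + 1L]] <- df
    }
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(nodule_id = character(0),
                    condition_index = integer(0),
                    reason = character(0), stringsAsFactors = FALSE))
}

.need_file <- function(out_dir, name, stage) {
  p <- file.path(out_dir, name)
  if (!file.exists(p))
    stop("stage '", stage, "' needs ", name,
         " - run the earlier stages first (missing: ", p, ")")
  p
}

#' Run the study pipeline
#'
#' Stages: `simulate` (writes the cohort description), `extract` (feature
#' table + exclusion log), `volumes` (per-nodule volume records),
#' `compare` (thickness p-value matrix and deviation summary), `map`
#' (compatibility map, per-feature robustness, pairwise axis tables),
#' `report` (figures + markdown summary), or `all`. Later stages read the
#' CSVs written by earlier ones, so a finished stage is never recomputed.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stage names, or "all".
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  stopifnot(inherits(config, "study_config"))
  all_stages <- c("simulate", "extract", "volumes", "compare", "map",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  cmt <- paste0("config_hash: ", hash)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  grid <- .cfg_grid(config)
  cohort <- NULL
  get_cohort <- function() {
    if (is.null(cohort)) cohort <<- .cfg_cohort(config)
    cohort
  }

  if ("simulate" %in% stages) {
    co <- get_cohort()
    specs <- do.call(rbind, lapply(seq_along(co$specs), function(i) {
      sp <- co$specs[[i]]
      data.frame(nodule_id = co$nodule_ids[i],
                 center_x = sp$nodule_center_mm[1],
                 center_y = sp$nodule_center_mm[2],
                 center_z = sp$nodule_center_mm[3],
                 semi_a = sp$semi_axes_mm[1], semi_b = sp$semi_axes_mm[2],
                 semi_c = sp$semi_axes_mm[3],
                 nodule_mean_hu = sp$nodule_mean_hu,
                 background_mean_hu = sp$background_mean_hu,
                 texture_seed = sp$seed, stringsAsFactors = FALSE)
    }))
    write_table(specs, file.path(out_dir, "cohort.csv"), cmt)
    write_table(grid, file.path(out_dir, "conditions.csv"), cmt)
  }

  if ("extract" %in% stages) {
    res <- cohort_feature_table(get_cohort(), .cfg_settings(config))
    if (is.null(res$features))
      stop("extraction produced no evaluable sample sets")
    write_table(res$features, file.path(out_dir, "features.csv"), cmt)
    write_table(res$exclusions, file.path(out_dir, "exclusions.csv"), cmt)
  }

  if ("volumes" %in% stages) {
    recs <- cohort_volume_records(get_cohort())
    if (length(recs) == 0) stop("no nodules usable for volumetry")
    vtab <- do.call(rbind, lapply(recs, function(r)
      data.frame(nodule_id = r$nodule_id, thickness_mm = r$thickness_mm,
                 volume_mm3 = r$volume_mm3, v_norm = r$v_norm,
                 stringsAsFactors = FALSE)))
    write_table(vtab, file.path(out_dir, "volumes.csv"), cmt)
  }

  if ("compare" %in% stages) {
    vtab <- read_table(.need_file(out_dir, "volumes.csv", "compare"))
    recs <- lapply(split(vtab, vtab$nodule_id), function(d) {
      d <- d[order(d$thickness_mm), ]
      normalize_volumes(stats::setNames(d$volume_mm3, d$thickness_mm),
                        nodule_id = d$nodule_id[1])
    })
    tc <- thickness_compatibility(unname(recs))
    pm <- as.data.frame(tc$p_matrix)
    pm <- cbind(data.frame(thickness_mm = as.numeric(rownames(tc$p_matrix))),
                pm)
    write_table(pm, file.path(out_dir, "thickness_p_matrix.csv"), cmt)
    write_table(tc$deviation,
                file.path(out_dir, "thickness_deviation.csv"), cmt)
  }

  if ("map" %in% stages) {
    tab <- read_table(.need_file(out_dir, "features.csv", "map"))
    sm <- feature_summaries(tab, grid)
    cm <- compatibility_map(sm)
    md <- as.data.frame(cm$cr)
    names(md) <- sprintf("cr_%03d", grid$index)
    md <- cbind(grid[, c("index", "dose_fraction", "kernel",
                         "thickness_mm")], md)
    write_table(md, file.path(out_dir, "compatibility_map.csv"), cmt)
    write_table(marginal_feature_robustness(sm),
                file.path(out_dir, "feature_robustness.csv"), cmt)
    axt <- pairwise_axis_tables(sm)
    for (ax in names(axt)) {
      d <- as.data.frame(axt[[ax]])
      d <- cbind(data.frame(value = rownames(axt[[ax]]),
                            stringsAsFactors = FALSE), d)
      write_table(d, file.path(out_dir,
                               sprintf("pairs_%s.csv", ax)), cmt)
    }
  }

  if ("report" %in% stages) {
    render_report(out_dir)
  }
  invisible(out_dir)
}
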