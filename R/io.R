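# Containers and on-disk formats: NIfTI volumes/masks, JSON/YAML cohort
# manifests, CSV tables. Masks must share the exact grid of the volume they
# are applied to; no resampling happens in I/O.

#' Image volume container
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing_mm length-3 positive spacing (in-plane x, in-plane y,
#'   slice thickness z).
#' @param origin_mm world position of the first voxel corner (default 0).
#' @param condition optional list/row with dose_fraction, kernel,
#'   thickness_mm; when set, the z spacing must equal the thickness.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                         condition = NULL) {
  if (length(dim(voxels)) != 3 || length(voxels) == 0)
    stop("voxels must be a non-empty 3-D array")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  if (!is.null(condition) &&
      abs(spacing_mm[3] - condition$thickness_mm) > 1e-6)
    stop("z spacing (", spacing_mm[3],
         ") must equal condition thickness (", condition$thickness_mm, ")")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 condition = condition),
            class = "image_volume")
}

#' ROI mask container
#'
#' @param voxels 3-D logical (or 0/1) array.
#' @param spacing_mm,origin_mm grid metadata, as in [image_volume()].
#' @param nodule_id identifier of the nodule the ROI delineates.
#' @param allow_empty if TRUE an all-FALSE mask is permitted and flagged
#'   (`$empty`), with a warning, instead of rejected.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                     nodule_id = NA_character_, allow_empty = FALSE) {
  if (length(dim(voxels)) != 3)
    stop("mask voxels must be a 3-D array")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask is not binary: values other than 0/1 present")
    voxels <- array(voxels == 1, dim = dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask voxels must be logical or 0/1")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  empty <- !any(voxels)
  if (empty && !allow_empty)
    stop("mask has no voxels inside the ROI")
  if (empty)
    warning("empty ROI mask for nodule ", nodule_id,
            " (nodule falls between slice centers)")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm), nodule_id = nodule_id,
                 empty = empty),
            class = "roi_mask")
}

.check_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("volume and mask shapes differ")
  if (any(abs(volume$spacing_mm - mask$spacing_mm) > 1e-6) ||
      any(abs(volume$origin_mm - mask$origin_mm) > 1e-6))
    stop("volume and mask grids differ (spacing/origin)")
  invisible(TRUE)
}

.nifti_from <- function(voxels, spacing_mm, origin_mm) {
  im <- RNifti::asNifti(voxels)
  mat <- diag(c(spacing_mm, 1))
  mat[1:3, 4] <- origin_mm
  RNifti::`sform<-`(im, structure(mat, code = 2L))
}

#' Write a volume or mask as NIfTI
#'
#' Spacing goes into the sform affine (code 2); masks are written as 0/1
#' integers, volumes as float64 so that round-trips are bit-identical.
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path) {
  vox <- if (inherits(x, "roi_mask")) array(as.integer(x$voxels),
                                            dim = dim(x$voxels)) else x$voxels
  im <- .nifti_from(vox, x$spacing_mm, x$origin_mm)
  RNifti::writeNifti(im, path,
                     datatype = if (inherits(x, "roi_mask")) "uint8"
                                else "double")
  invisible(path)
}

.read_nifti_grid <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- RNifti::xform(im, useQuaternionFirst = FALSE)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (all(spacing == 1)) {
    pd <- RNifti::pixdim(im)
    if (length(pd) >= 3 && all(pd[1:3] > 0)) spacing <- pd[1:3]
  }
  list(voxels = array(as.numeric(im), dim = dim(im)),
       spacing = as.numeric(spacing), origin = as.numeric(aff[1:3, 4]))
}

#' Read a NIfTI volume
#' @param path NIfTI file.
#' @param condition optional condition metadata to attach.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, condition = NULL) {
  g <- .read_nifti_grid(path)
  image_volume(g$voxels, g$spacing, g$origin, condition)
}

#' Read a NIfTI ROI mask
#'
#' Values must be exactly 0/1; anything else is rejected as non-binary.
#'
#' @param path NIfTI file.
#' @param nodule_id identifier to attach.
#' @param allow_empty passed to [roi_mask()].
#' @return an [roi_mask()].
#' @export
read_mask <- function(path, nodule_id = NA_character_, allow_empty = FALSE) {
  g <- .read_nifti_grid(path)
  roi_mask(g$voxels, g$spacing, g$origin, nodule_id = nodule_id,
           allow_empty = allow_empty)
}

#' Export a simulated cohort to disk
#'
#' Writes every (nodule, condition) volume and (nodule, thickness) reference
#' mask as NIfTI under `dir`, plus a `manifest.json` describing the layout
#' (condition grid with indices, file paths, seeds, model parameters) that
#' [load_manifest()] accepts.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ct_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$grid
  nodules <- lapply(seq_along(cohort$nodule_ids), function(i) {
    id <- cohort$nodule_ids[i]
    vols <- lapply(seq_len(nrow(grid)), function(ci) {
      p <- sprintf("%s_cond%03d.nii.gz", id, grid$index[ci])
      write_volume(cohort$render(i, grid$index[ci]), file.path(dir, p))
      list(condition_index = grid$index[ci], path = p)
    })
    msk <- lapply(names(cohort$masks[[i]]), function(th) {
      p <- sprintf("%s_mask_t%s.nii.gz", id, gsub("[.]", "p", th))
      write_volume(cohort$masks[[i]][[th]], file.path(dir, p))
      list(thickness_mm = as.numeric(th), path = p)
    })
    list(nodule_id = id, volumes = vols, masks = msk)
  })
  manifest <- list(
    master_seed = cohort$master_seed,
    model = list(base_noise_sd_hu = cohort$model$base_noise_sd_hu,
                 ir_noise_factor = cohort$model$ir_noise_factor),
    grid = grid[, c("index", "dose_fraction", "kernel", "thickness_mm")],
    nodules = nodules)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' The manifest (JSON or YAML) lists the condition grid and, per nodule, one
#' volume path per condition and exactly one mask path per thickness (the
#' reference-ROI design: a single per-thickness mask is shared by all
#' dose/kernel combinations at that thickness). Validation is total: any
#' missing (nodule, condition) cell or duplicate per-thickness mask aborts
#' the load with all offending cells enumerated.
#'
#' @param path manifest file (.json, .yaml or .yml).
#' @return list with `grid` (data.frame) and `nodules` (list of nodule_id,
#'   volumes data.frame, masks data.frame).
#' @export
load_manifest <- function(path) {
  raw <- if (grepl("[.](yaml|yml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$grid) || is.null(raw$nodules))
    stop("manifest must contain 'grid' and 'nodules'")
  grid <- if (is.data.frame(raw$grid)) as.data.frame(raw$grid)
    else do.call(rbind, lapply(raw$grid, as.data.frame))
  need <- c("index", "dose_fraction", "kernel", "thickness_mm")
  if (!all(need %in% names(grid)))
    stop("manifest grid needs columns ", paste(need, collapse = ", "))
  thicknesses <- sort(unique(grid$thickness_mm))
  # yaml gives a list of lists; jsonlite a data.frame - normalize
  nod_list <- if (is.data.frame(raw$nodules))
    split(raw$nodules, seq_len(nrow(raw$nodules)))
  else raw$nodules
  errors <- character(0)
  nodules <- lapply(nod_list, function(nd) {
    id <- nd$nodule_id
    vols <- as.data.frame(if (is.data.frame(nd$volumes[[1]]))
      nd$volumes[[1]] else do.call(rbind, lapply(nd$volumes, as.data.frame)))
    msks <- as.data.frame(if (is.data.frame(nd$masks[[1]]))
      nd$masks[[1]] else do.call(rbind, lapply(nd$masks, as.data.frame)))
    missing <- setdiff(grid$index, vols$condition_index)
    if (length(missing)) {
      mrows <- grid[grid$index %in% missing, ]
      errors <<- c(errors, sprintf(
        "nodule %s: missing volume for condition %d (%s)",
        id, mrows$index, condition_label(mrows)))
    }
    dup <- msks$thickness_mm[duplicated(msks$thickness_mm)]
    if (length(dup))
      errors <<- c(errors, sprintf(
        "nodule %s: duplicate mask for thickness %g mm", id, unique(dup)))
    mmiss <- setdiff(thicknesses, msks$thickness_mm)
    if (length(mmiss))
      errors <<- c(errors, sprintf(
        "nodule %s: missing mask for thickness %g mm", id, mmiss))
    list(nodule_id = id, volumes = vols, masks = msks)
  })
  if (length(errors))
    stop("invalid manifest:\n", paste(errors, collapse = "\n"))
  list(grid = grid, nodules = unname(nodules))
}

#' Write a data frame as CSV (lossless floats)
#'
#' Numeric columns are serialized with 17 significant digits so that
#' write/read round-trips reproduce doubles exactly. Optional comment lines
#' (e.g. a config hash) are prefixed with `#` and skipped by
#' [read_table()].
#'
#' @param df data.frame.
#' @param path output path.
#' @param comments character vector of comment lines (without the `#`).
#' @return the path, invisibly.
#' @export
write_table <- function(df, path, comments = NULL) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(names(df), collapse = ","),
    if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
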