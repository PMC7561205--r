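# Figures and the markdown summary rendered from a finished pipeline
# output directory.

.gg_save <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width * 100, height = height * 100,
                 res = 100, type = "cairo")
  print(plot)
  grDevices::dev.off()
  invisible(path)
}

# red-green diverging fill centered on the 5% significance boundary for
# p-values, or on 50% for compatibility percentages
.heat <- function(df, x, y, fill, title, midpoint, limits = NULL) {
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]],
                                   fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#c0392b", mid = "#f5d76e",
                                  high = "#1e8449", midpoint = midpoint,
                                  limits = limits) +
    ggplot2::labs(title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Render figures and summary from pipeline outputs
#'
#' Emits the normalized-volume trend plot, the thickness p-value heatmap,
#' the compatibility-map heatmap (rows/columns in the report sort order:
#' thickness 5 to 0.6 mm, kernels smoothest-iterative to sharpest-FBP, dose
#' 100 down to 12.5%), per-feature robustness bars, the three pairwise-axis
#' heatmaps, and `summary.md`.
#'
#' @param out_dir a directory holding the CSVs written by [run_pipeline()].
#' @return character vector of figure paths, invisibly.
#' @export
render_report <- function(out_dir) {
  figs <- character(0)

  vtab <- read_table(.need_file(out_dir, "volumes.csv", "report"))
  p1 <- ggplot2::ggplot(vtab,
                        ggplot2::aes(thickness_mm, v_norm,
                                     group = nodule_id,
                                     colour = nodule_id)) +
    ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(title = "Normalized nodule volume by slice thickness",
                  x = "slice thickness (mm)", y = "V / mean(V)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  figs <- c(figs, .gg_save(p1, file.path(out_dir, "fig_vnorm_trend.png")))

  pm <- read_table(.need_file(out_dir, "thickness_p_matrix.csv", "report"))
  long <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
    data.frame(t1 = pm$thickness_mm[i],
               t2 = pm$thickness_mm,
               p = as.numeric(pm[i, -1]))
  }))
  long$t1 <- factor(long$t1, levels = sort(unique(long$t1)))
  long$t2 <- factor(long$t2, levels = sort(unique(long$t2)))
  figs <- c(figs, .gg_save(
    .heat(long, "t1", "t2", "p",
          "Thickness compatibility of normalized volumes (p-values)",
          midpoint = 0.05) +
      ggplot2::labs(x = "thickness (mm)", y = "thickness (mm)"),
    file.path(out_dir, "fig_thickness_p.png")))

  md <- read_table(.need_file(out_dir, "compatibility_map.csv", "report"))
  crcols <- grep("^cr_", names(md))
  grid <- md[, c("index", "dose_fraction", "kernel", "thickness_mm")]
  ord <- condition_sort_order(grid)
  lab <- condition_label(grid)
  cr <- as.matrix(md[, crcols])
  cr <- cr[ord, ord]
  mlong <- data.frame(
    i = factor(rep(lab[ord], times = length(ord)),
               levels = lab[ord]),
    j = factor(rep(lab[ord], each = length(ord)),
               levels = rev(lab[ord])),
    cr = as.vector(cr))
  figs <- c(figs, .gg_save(
    .heat(mlong, "i", "j", "cr",
          "Reconstruction-condition compatibility map (% compatible)",
          midpoint = 50, limits = c(0, 100)),
    file.path(out_dir, "fig_compatibility_map.png"),
    width = 9, height = 8))

  fr <- read_table(.need_file(out_dir, "feature_robustness.csv", "report"))
  fr$feature <- factor(fr$feature, levels = rev(feature_names()))
  p4 <- ggplot2::ggplot(fr, ggplot2::aes(pct_compatible, feature,
                                         fill = group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(title = "Feature robustness to single-axis changes",
                  x = "% compatible (pair, patient) cells", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
  figs <- c(figs, .gg_save(p4, file.path(out_dir,
                                         "fig_feature_robustness.png"),
                           width = 9, height = 6))

  for (ax in c("kernel", "thickness", "dose")) {
    d <- read_table(.need_file(out_dir, sprintf("pairs_%s.csv", ax),
                               "report"))
    vals <- as.character(d$value)
    long <- data.frame(a = factor(rep(vals, times = length(vals)),
                                  levels = vals),
                       b = factor(rep(vals, each = length(vals)),
                                  levels = rev(vals)),
                       pct = as.vector(as.matrix(d[, -1])))
    figs <- c(figs, .gg_save(
      .heat(long, "a", "b", "pct",
            sprintf("Compatible features across %s pairs (%%)", ax),
            midpoint = 50, limits = c(0, 100)),
      file.path(out_dir, sprintf("fig_pairs_%s.png", ax))))
  }

  dev <- read_table(file.path(out_dir, "thickness_deviation.csv"))
  best <- dev[which.min(abs(dev$mean_pct)), ]
  lines <- c(
    "# Study summary", "",
    sprintf("- Conditions: %d; nodules: %d.", nrow(grid),
            length(unique(vtab$nodule_id))),
    sprintf("- Thickness with smallest mean volumetric deviation: %g mm (%+.2f%% +/- %.2f).",
            best$thickness_mm, best$mean_pct, best$sd_pct),
    sprintf("- Compatibility-map range: %.2f%% to %.2f%% (diagonal %.1f%%).",
            min(cr, na.rm = TRUE), max(cr, na.rm = TRUE),
            mean(diag(cr), na.rm = TRUE)),
    "", "Figures:", paste0("- ", basename(figs)))
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(figs)
}
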