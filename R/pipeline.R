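#' Quantify one multi-channel image
#'
#' Segments nuclei from the DNA channel and cells from the cytosolic
#' marker, estimates the background per channel, and computes the requested
#' per-cell metrics. Cells whose metric is undefined (non-positive
#' denominator) are excluded and reported in the log, never imputed.
#'
#' @param channels named list of [channel_image()]s.
#' @param metrics character vector from `cn_ratio`, `nc_gradient`,
#'   `laminar_intensity`, `envelope_to_nucleoplasm_ratio`, `continuity`,
#'   `puncta_count`, `circularity`.
#' @param measure_channel channel the metrics are computed on.
#' @param dna_channel channel defining nuclear boundaries.
#' @param marker_channel channel defining cytosolic boundaries (defaults to
#'   `measure_channel`).
#' @param config a `run_config` ([default_config()]).
#' @return `list(measurements = data.frame(cell, metric, value, background),
#'   log = character())`.
#' @export
quantify_image <- function(channels, metrics, measure_channel,
                           dna_channel = "DNA", marker_channel = measure_channel,
                           config = default_config()) {
  stopifnot(dna_channel %in% names(channels),
            measure_channel %in% names(channels),
            marker_channel %in% names(channels))
  log <- character(0)
  nuclei <- segment_nuclei(channels[[dna_channel]],
                           min_area_um2 = config$nucleus_min_area_um2,
                           method = config$threshold_method,
                           value = config$threshold_value)
  if (length(nuclei) == 0)
    return(list(measurements = NULL, log = "no nuclei detected"))
  cells <- withCallingHandlers(
    segment_cell(channels[[marker_channel]], nuclei,
                 method = config$threshold_method,
                 value = config$threshold_value),
    warning = function(w) {
      log <<- c(log, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  img <- channels[[measure_channel]]
  ps <- img$pixel_size
  bg <- if (isTRUE(config$subtract_background))
    as.numeric(estimate_background(img, lapply(cells, `[[`, "cell_mask"),
                                   guard_px = config$background_guard_px,
                                   stat = config$background_stat)) else 0
  rows <- list()
  add <- function(cell, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cell = cell, metric = metric, value = value, background = bg)
  }
  for (cell in cells) {
    for (metric in metrics) {
      value <- withCallingHandlers(
        switch(metric,
          cn_ratio = cn_ratio(img, cell, bg),
          nc_gradient = nc_gradient(img, cell, bg),
          laminar_intensity = {
            ring <- make_ring(cell$nucleus_mask, config$ring_outer_um,
                              config$ring_inner_um, ps)
            laminar_intensity(img, ring, bg)
          },
          envelope_to_nucleoplasm_ratio =
            envelope_to_nucleoplasm_ratio(img, cell$nucleus_mask,
                                          band_px = config$envelope_band_px,
                                          erode_px = config$nucleoplasm_erode_px),
          continuity = {
            prof <- envelope_profile(img, cell$nucleus_mask, config$ring_outer_um)
            th <- config$continuity_threshold
            if (is.null(th)) {
              ring <- make_ring(cell$nucleus_mask, config$ring_outer_um,
                                config$ring_inner_um, ps)
              th <- continuity_threshold(img, ring, bg)
            }
            continuity_index(prof, th)$index
          },
          puncta_count = {
            th <- config$puncta_threshold
            if (is.null(th)) th <- bg + 0.5 * (max(img$pixels) - bg)
            p <- detect_puncta(img, region_mask = cell$cytosol_mask,
                               intensity_threshold = th,
                               min_area_um2 = config$puncta_min_area_um2,
                               max_area_um2 = config$puncta_max_area_um2)
            puncta_count(p)
          },
          circularity = circularity(cell$nucleus_mask, ps),
          stop(sprintf("unknown metric '%s'", metric))),
        warning = function(w) {
          log <<- c(log, sprintf("cell %s, %s: %s", cell$cell_id, metric,
                                 conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (is.na(value)) {
        log <- c(log, sprintf("cell %s: %s undefined, row excluded",
                              cell$cell_id, metric))
      } else add(cell$cell_id, metric, value)
    }
  }
  list(measurements = if (length(rows)) do.call(rbind, rows) else NULL,
       log = log)
}

#' Run the full pipeline over a sample sheet
#'
#' simulate/acquire -> segment -> quantify -> normalize -> clustered rank
#' statistics, mirroring the per-figure workflow: per-cell metrics,
#' normalization to the control-group mean within each experiment, then a
#' cluster-robust rank test across groups. Deterministic for fixed inputs
#' and configuration; outputs are written atomically.
#'
#' @param sample_sheet data.frame from [read_sample_sheet()] (or a path).
#' @param metrics metric names, as in [quantify_image()].
#' @param measure_channel channel the metrics are computed on.
#' @param config a `run_config`.
#' @param control_group control level for normalization; `NULL` skips
#'   normalization.
#' @param out_dir optional directory for `measurements.csv`,
#'   `stats_<metric>.csv`, `report.txt`, `config.yml` and `log.txt`.
#' @return `list(measurements, tests, report, log)`.
#' @export
run_pipeline <- function(sample_sheet, metrics = "cn_ratio",
                         measure_channel, config = default_config(),
                         control_group = NULL, out_dir = NULL) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (nrow(sample_sheet) == 0) stop("sample sheet is empty")
  all_rows <- list(); log <- character(0)
  for (i in seq_len(nrow(sample_sheet))) {
    row <- sample_sheet[i, ]
    channels <- tryCatch(read_image(row$image),
                         error = function(e)
                           stop(sprintf("image '%s': %s", row$image,
                                        conditionMessage(e))))
    marker <- if (!is.null(row$marker_channel)) row$marker_channel else measure_channel
    q <- quantify_image(channels, metrics, measure_channel,
                        dna_channel = row$dna_channel,
                        marker_channel = marker, config = config)
    if (length(q$log))
      log <- c(log, sprintf("[%s] %s", basename(row$image), q$log))
    if (!is.null(q$measurements)) {
      m <- q$measurements
      m$image <- basename(row$image)
      m$group <- row$group; m$cluster <- row$cluster
      m$experiment <- row$experiment
      all_rows[[length(all_rows) + 1L]] <- m
    }
  }
  if (!length(all_rows)) stop("no cells were quantified")
  tab <- do.call(rbind, all_rows)
  tab <- tab[, c("image", "cell", "group", "cluster", "experiment",
                 "metric", "value", "background")]
  if (!is.null(control_group)) {
    for (metric in unique(tab$metric)) {
      sel <- tab$metric == metric
      tab[sel, ] <- normalize_to_control(tab[sel, ], control_group)
    }
  }
  tests <- list()
  for (metric in unique(tab$metric)) {
    sub <- tab[tab$metric == metric, ]
    n_groups <- length(unique(sub$group))
    if (n_groups < 2) next
    tests[[metric]] <- if (n_groups == 2)
      cluster_robust_rank_ttest(sub, "value", "group", "cluster",
                                alpha = config$alpha,
                                type = config$variance_estimator)
    else
      cluster_robust_rank_anova(sub, "value", "group", "cluster",
                                alpha = config$alpha,
                                type = config$variance_estimator,
                                adjust = config$adjust)
  }
  report <- write_report(list(measurements = tab, tests = tests))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_atomic <- function(writer, file) {
      tmp <- paste0(file, ".tmp")
      writer(tmp)
      file.rename(tmp, file)
    }
    .write_atomic(function(f) utils::write.csv(tab, f, row.names = FALSE),
                  file.path(out_dir, "measurements.csv"))
    for (metric in names(tests))
      .write_atomic(function(f) utils::write.csv(
        cbind(metric = metric, tests[[metric]]$contrasts), f, row.names = FALSE),
        file.path(out_dir, sprintf("stats_%s.csv", metric)))
    .write_atomic(function(f) writeLines(report, f), file.path(out_dir, "report.txt"))
    .write_atomic(function(f) writeLines(log, f), file.path(out_dir, "log.txt"))
    save_config(config, file.path(out_dir, "config.yml"))
  }
  list(measurements = tab, tests = tests, report = report, log = log)
}

#' Render a human-readable summary report
#'
#' Per-metric, per-group summaries in the box-plot convention (quartiles,
#' median, 10-90 range) plus omnibus and pairwise test lines with
#' significance stars.
#'
#' @param results `list(measurements =, tests =)` as produced by
#'   [run_pipeline()].
#' @return character vector of report lines.
#' @export
write_report <- function(results) {
  tab <- results$measurements
  lines <- character(0)
  if (is.null(tab) || nrow(tab) == 0)
    return("no measurements (empty results)")
  for (metric in unique(tab$metric)) {
    sub <- tab[tab$metric == metric, ]
    lines <- c(lines, sprintf("== %s ==", metric))
    for (g in sort(unique(sub$group))) {
      v <- sub$value[sub$group == g]
      q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
      lines <- c(lines, sprintf(
        "  %s: n = %d, median = %.4g, quartiles [%.4g, %.4g], 10-90 range [%.4g, %.4g]",
        g, length(v), q[3], q[2], q[4], q[1], q[5]))
    }
    tst <- results$tests[[metric]]
    if (!is.null(tst)) {
      lines <- c(lines, sprintf("  omnibus: F(%g, %g) = %.4g, p = %.4g %s",
                                tst$omnibus$df1, tst$omnibus$df2,
                                tst$omnibus$statistic, tst$omnibus$p,
                                sig_stars(tst$omnibus$p)))
      ct <- tst$contrasts
      for (i in seq_len(nrow(ct)))
        lines <- c(lines, sprintf("  %s vs %s: adj p = %.4g %s",
                                  ct$group1[i], ct$group2[i], ct$p_adj[i],
                                  sig_stars(ct$p_adj[i])))
    }
  }
  lines
}
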