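# Intensities are stored in 16-bit TIFF as value / 65535; scenes therefore
# keep planted levels below 65535. A YAML sidecar per image carries the
# pixel size and channel names (r-tiff cannot embed descriptive tags).

#' Write a scene as a multi-page 16-bit TIFF plus sidecar metadata
#'
#' One page per channel, intensities rounded to integers; a `<image>.yml`
#' sidecar records pixel size and channel order, and the ground truth is
#' written as plain CSV tables alongside.
#'
#' @param scene a [generate_scene()] result.
#' @param path output TIFF path (`.tif`).
#' @param ground_truth also write `<base>_truth_*.csv` tables.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path, ground_truth = TRUE) {
  stopifnot(inherits(scene, "scene"))
  pages <- lapply(scene$channels, function(ch) {
    m <- round(ch$pixels)
    if (max(m) > 65535) stop("intensity exceeds the 16-bit range")
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = scene$spec$pixel_size,
               channels = names(scene$channels),
               bits_per_sample = 16L)
  yaml::write_yaml(meta, paste0(tools::file_path_sans_ext(path), ".yml"))
  if (ground_truth) {
    base <- tools::file_path_sans_ext(path)
    gt <- scene$ground_truth
    utils::write.csv(gt$cells, paste0(base, "_truth_cells.csv"), row.names = FALSE)
    if (!is.null(gt$cn))
      utils::write.csv(gt$cn, paste0(base, "_truth_cn.csv"), row.names = FALSE)
    if (!is.null(gt$puncta))
      utils::write.csv(gt$puncta, paste0(base, "_truth_puncta.csv"), row.names = FALSE)
    if (!is.null(gt$overlap))
      utils::write.csv(gt$overlap, paste0(base, "_truth_overlap.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a multi-channel image
#'
#' Reads a (multi-page) TIFF; channel names and pixel size come from the
#' YAML sidecar written by [write_scene()] when present. A `pixel_size`
#' argument overrides the sidecar (with a warning); with neither, the
#' function errors rather than assuming a default.
#'
#' @param path TIFF path.
#' @param pixel_size optional micrometres-per-pixel override.
#' @param channels optional channel names (recycled over pages).
#' @return named list of [channel_image()]s, intensities on the original
#'   integer scale.
#' @export
read_image <- function(path, pixel_size = NULL, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".yml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  ps <- meta$pixel_size_um
  if (!is.null(pixel_size)) {
    if (!is.null(ps) && !isTRUE(all.equal(ps, pixel_size)))
      warning(sprintf("pixel_size override %.4g um/px replaces sidecar value %.4g",
                      pixel_size, ps))
    ps <- pixel_size
  }
  if (is.null(ps))
    stop(sprintf("no pixel size for '%s': no sidecar metadata and no pixel_size argument",
                 path))
  nm <- channels
  if (is.null(nm)) nm <- meta$channels
  if (is.null(nm)) nm <- paste0("ch", seq_along(pages))
  if (length(nm) != length(pages))
    stop(sprintf("%d channel names for %d pages in '%s'",
                 length(nm), length(pages), path))
  out <- list()
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    out[[nm[i]]] <- channel_image(round(m * 65535), ps, nm[i])
  }
  out
}

#' Default run configuration
#'
#' Every tunable of the quantification pipeline with its default: the
#' thresholds, offsets (um), puncta constraints, continuity threshold rule,
#' variance estimator and significance level.
#'
#' @return named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    nucleus_min_area_um2 = 10,
    threshold_method = "otsu",
    threshold_value = NULL,
    ring_outer_um = 1.3,
    ring_inner_um = 0,
    perinuclear_band_um = 4.5,
    envelope_band_px = 1,
    nucleoplasm_erode_px = 2,
    background_guard_px = 2,
    background_stat = "median",
    subtract_background = TRUE,
    puncta_threshold = NULL,
    puncta_min_area_um2 = 0.1,
    puncta_max_area_um2 = 10,
    puncta_min_roundness = 0.6,
    puncta_max_dist_to_envelope_um = 2,
    continuity_threshold = NULL,
    coloc_threshold_a = NULL,
    coloc_threshold_b = NULL,
    variance_estimator = "CR2",
    adjust = "tukey",
    alpha = 0.05,
    seed = 1
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults. The
#' configuration round-trips losslessly through [save_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' CSV with one row per image: `image` (path), `group`, `cluster`,
#' `experiment`, plus `dna_channel` and `marker_channel` naming the
#' channels used for nuclear and cytosolic boundaries.
#'
#' @param path CSV path.
#' @param check_paths verify that every image file exists.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path, check_paths = TRUE) {
  ss <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image", "group", "cluster", "experiment")
  missing <- setdiff(required, names(ss))
  if (length(missing))
    stop(sprintf("sample sheet lacks columns: %s", paste(missing, collapse = ", ")))
  if (nrow(ss) == 0) stop("sample sheet is empty")
  if (any(ss$group == "" | ss$cluster == "" | ss$experiment == ""))
    stop("group, cluster and experiment must be non-empty")
  if (check_paths) {
    bad <- ss$image[!file.exists(ss$image)]
    if (length(bad))
      stop(sprintf("missing image files: %s", paste(bad, collapse = ", ")))
  }
  if (is.null(ss$dna_channel)) ss$dna_channel <- "DNA"
  ss
}
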