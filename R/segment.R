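# Automatic / fixed / percentile thresholding shared by the segmentation ops.
.threshold_value <- function(pixels, method = c("otsu", "fixed", "percentile"),
                             value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("fixed thresholding requires a value")
    return(value)
  }
  if (method == "percentile") {
    if (is.null(value)) stop("percentile thresholding requires a value in (0, 100)")
    return(as.numeric(stats::quantile(pixels, value / 100, names = FALSE)))
  }
  rng <- range(pixels)
  if (diff(rng) == 0) stop("no threshold separates foreground: image is constant")
  x01 <- (pixels - rng[1]) / diff(rng)
  th01 <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1), levels = 256)
  rng[1] + th01 * diff(rng)
}

#' Segment nuclei from a DNA-stain channel
#'
#' Global automatic threshold (default Otsu), hole filling, removal of
#' components below a minimum area, and labelling. The DNA stain is the
#' reference for nuclear boundaries.
#'
#' @param dna [channel_image()] of the DNA counterstain.
#' @param min_area_um2 minimum component area in square micrometres.
#' @param method `"otsu"` (default), `"fixed"` or `"percentile"`.
#' @param value threshold intensity (`fixed`) or percentile (`percentile`).
#' @return list of disjoint logical nucleus masks, ordered by component
#'   label.
#' @export
segment_nuclei <- function(dna, min_area_um2 = 10, method = "otsu", value = NULL) {
  dna <- .as_channel(dna)
  th <- .threshold_value(dna$pixels, method, value)
  fg <- dna$pixels > th
  fg <- .ebi_mat(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  lab <- .ebi_mat(EBImage::bwlabel(EBImage::Image(fg * 1)))
  min_px <- min_area_um2 / dna$pixel_size^2
  masks <- list()
  for (k in seq_len(max(lab))) {
    m <- lab == k
    if (sum(m) >= min_px) masks[[length(masks) + 1L]] <- m
  }
  masks
}

#' Segment whole cells around nuclei from a cytosolic marker
#'
#' Thresholds the marker channel (the cytosolic boundary reference, e.g.
#' ChAT/NeuN), assigns each foreground component to the nuclei it contains,
#' and splits components holding several nuclei by a geodesic
#' nearest-nucleus partition. Each returned cell mask contains its nucleus
#' (union-enforced); foreground components without a nucleus are discarded.
#'
#' @param marker [channel_image()] of the cytosolic marker.
#' @param nuclei list of nucleus masks ([segment_nuclei()] output).
#' @param method,value thresholding, as in [segment_nuclei()].
#' @return list of [segmented_cell()] objects, one per nucleus with marker
#'   support; a warning is emitted for cells whose cytosol is empty.
#' @export
segment_cell <- function(marker, nuclei, method = "otsu", value = NULL) {
  marker <- .as_channel(marker)
  if (length(nuclei) == 0) stop("at least one nucleus mask is required")
  th <- .threshold_value(marker$pixels, method, value)
  fg <- marker$pixels > th
  seeds <- matrix(0L, nrow(fg), ncol(fg))
  for (i in seq_along(nuclei)) seeds[nuclei[[i]]] <- i
  fg <- fg | seeds > 0
  # geodesic Voronoi: constant intensity makes propagate() a pure
  # nearest-seed partition restricted to the foreground
  lab <- .ebi_mat(EBImage::propagate(
    EBImage::Image(matrix(0, nrow(fg), ncol(fg))),
    seeds = EBImage::Image(seeds), mask = EBImage::Image(fg * 1)))
  cells <- list()
  for (i in seq_along(nuclei)) {
    cm <- (lab == i) | nuclei[[i]]
    if (!any(cm & !nuclei[[i]]))
      warning(sprintf("cell %d: no cytosolic marker foreground beyond the nucleus (empty cytosol)", i))
    cells[[length(cells) + 1L]] <- segmented_cell(i, nuclei[[i]], cm)
  }
  cells
}

#' Build an envelope ring (annulus) around a nucleus
#'
#' `ring = dilate(nucleus, outer) AND NOT dilate(nucleus, inner)`, with
#' Euclidean disk dilation of radius `round(offset / pixel_size)` pixels
#' (half-up). The default laminar ring is inner 0 um, outer 1.3 um: the
#' nucleus boundary dilated by 1.3 um, nucleus interior excluded.
#'
#' @param nucleus_mask logical matrix.
#' @param outer_offset_um,inner_offset_um offsets in micrometres
#'   (`outer > inner >= 0`).
#' @param pixel_size micrometres per pixel.
#' @return logical ring mask.
#' @export
make_ring <- function(nucleus_mask, outer_offset_um = 1.3,
                      inner_offset_um = 0, pixel_size = 1) {
  stopifnot(is.matrix(nucleus_mask))
  if (inner_offset_um < 0 || outer_offset_um < 0) stop("offsets must be >= 0")
  if (outer_offset_um <= inner_offset_um)
    stop("outer offset must exceed inner offset")
  r_out <- um_to_px(outer_offset_um, pixel_size)
  r_in <- um_to_px(inner_offset_um, pixel_size)
  if (r_out <= r_in)
    stop(sprintf(paste0("offsets %.3g and %.3g um round to the same pixel radius; ",
                        "the minimum resolvable offset difference is %.3g um (one pixel)"),
         inner_offset_um, outer_offset_um, pixel_size))
  outer <- dilate_mask(nucleus_mask, r_out)
  inner <- if (r_in > 0) dilate_mask(nucleus_mask, r_in) else nucleus_mask
  outer & !inner
}

#' Perinuclear cytoplasmic band
#'
#' A band of the given width immediately surrounding the nucleus (inner
#' offset 0): the region used for cytoplasmic XPO1 in postmortem tissue,
#' where the full cytosol is not delineated.
#'
#' @param nucleus_mask logical matrix.
#' @param width_um band width in micrometres.
#' @param pixel_size micrometres per pixel.
#' @return logical band mask (disjoint from the nucleus).
#' @export
perinuclear_band <- function(nucleus_mask, width_um, pixel_size = 1) {
  make_ring(nucleus_mask, outer_offset_um = width_um,
            inner_offset_um = 0, pixel_size = pixel_size)
}

#' Estimate the image background level
#'
#' Default: median intensity outside the union of all cell masks dilated by
#' a 2-pixel guard band.
#'
#' @param image [channel_image()] or matrix.
#' @param cell_masks list of logical cell masks (may be empty).
#' @param guard_px guard band in pixels around cells.
#' @param stat `"median"` or `"mean"`.
#' @return background intensity, with attributes `statistic` and
#'   `n_pixels`.
#' @export
estimate_background <- function(image, cell_masks = list(), guard_px = 2,
                                stat = c("median", "mean")) {
  stat <- match.arg(stat)
  image <- .as_channel(image, pixel_size = 1)
  px <- image$pixels
  if (length(cell_masks) > 0) {
    u <- Reduce(`|`, cell_masks)
    u <- dilate_mask(u, guard_px)
    bg <- px[!u]
  } else bg <- as.vector(px)
  if (length(bg) == 0)
    stop("no background pixels outside the cell masks; supply a manual background value")
  v <- if (stat == "median") stats::median(bg) else mean(bg)
  structure(v, statistic = stat, n_pixels = length(bg))
}
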