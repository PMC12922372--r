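.masked_mean <- function(pixels, mask) mean(pixels[mask])

#' Cytosol-to-nucleus intensity ratio
#'
#' Background-subtracted mean cytosolic intensity divided by
#' background-subtracted mean nuclear intensity for one cell: the C/N ratio
#' used for markers such as SOD1-GFP, XPO1 and RanGAP1.
#'
#' @param image [channel_image()] or matrix.
#' @param cell [segmented_cell()] with non-empty nucleus and cytosol.
#' @param background scalar background intensity to subtract.
#' @return the ratio, or `NA` (with a warning) when the nuclear mean after
#'   background subtraction is not positive; undefined values are never
#'   clipped or imputed.
#' @export
cn_ratio <- function(image, cell, background = 0) {
  image <- .as_channel(image, pixel_size = 1)
  if (!any(cell$cytosol_mask)) stop("cytosol mask is empty")
  if (!any(cell$nucleus_mask)) stop("nucleus mask is empty")
  num <- .masked_mean(image$pixels, cell$cytosol_mask) - background
  den <- .masked_mean(image$pixels, cell$nucleus_mask) - background
  if (den <= 0) {
    warning(sprintf("cell %s: background-subtracted nuclear mean <= 0; C/N undefined",
                    as.character(cell$cell_id)))
    return(NA_real_)
  }
  num / den
}

#' Nucleus-to-cytosol intensity ratio
#'
#' The reciprocal orientation of [cn_ratio()], used for the Ran gradient
#' (nuclear-high in healthy cells).
#'
#' @inheritParams cn_ratio
#' @return the ratio, or `NA` with a warning when the cytosolic mean after
#'   background subtraction is not positive.
#' @export
nc_gradient <- function(image, cell, background = 0) {
  image <- .as_channel(image, pixel_size = 1)
  if (!any(cell$cytosol_mask)) stop("cytosol mask is empty")
  if (!any(cell$nucleus_mask)) stop("nucleus mask is empty")
  num <- .masked_mean(image$pixels, cell$nucleus_mask) - background
  den <- .masked_mean(image$pixels, cell$cytosol_mask) - background
  if (den <= 0) {
    warning(sprintf("cell %s: background-subtracted cytosolic mean <= 0; N/C undefined",
                    as.character(cell$cell_id)))
    return(NA_real_)
  }
  num / den
}

#' Laminar (nuclear-envelope ring) intensity
#'
#' Mean intensity over the envelope ring mask minus background. The value
#' may be negative (flagged by the caller, never clipped).
#'
#' @param image [channel_image()] or matrix.
#' @param ring_mask logical annulus mask ([make_ring()]).
#' @param background scalar background intensity.
#' @return background-subtracted mean ring intensity.
#' @export
laminar_intensity <- function(image, ring_mask, background = 0) {
  image <- .as_channel(image, pixel_size = 1)
  if (!any(ring_mask)) stop("ring mask is empty")
  .masked_mean(image$pixels, ring_mask) - background
}

#' Envelope-to-nucleoplasm intensity ratio
#'
#' Mean intensity of a thin (default 1-pixel) band around the nuclear
#' boundary divided by the mean nucleoplasm intensity (the nucleus eroded
#' clear of the envelope). The nucleoplasm acts as the per-cell normalizer,
#' as in postmortem-tissue nuclear-pore quantification; no separate
#' background is subtracted.
#'
#' @param image [channel_image()] or matrix.
#' @param nucleus_mask logical nucleus mask (or a [segmented_cell()]).
#' @param band_px envelope band width in pixels (outside the boundary).
#' @param erode_px erosion radius defining the nucleoplasm.
#' @return the ratio, or `NA` with a warning when the nucleus is too small
#'   to erode or the nucleoplasm mean is not positive.
#' @export
envelope_to_nucleoplasm_ratio <- function(image, nucleus_mask,
                                          band_px = 1, erode_px = 2) {
  image <- .as_channel(image, pixel_size = 1)
  if (inherits(nucleus_mask, "segmented_cell")) nucleus_mask <- nucleus_mask$nucleus_mask
  band <- dilate_mask(nucleus_mask, band_px) & !nucleus_mask
  nucleoplasm <- erode_mask(nucleus_mask, erode_px)
  if (!any(nucleoplasm)) {
    warning("nucleus too small to erode a nucleoplasm region; ratio undefined")
    return(NA_real_)
  }
  den <- .masked_mean(image$pixels, nucleoplasm)
  if (den <= 0) {
    warning("nucleoplasm mean intensity <= 0; ratio undefined")
    return(NA_real_)
  }
  .masked_mean(image$pixels, band) / den
}

#' Detect puncta by intensity threshold with size and shape constraints
#'
#' Connected components of `image > intensity_threshold` within a region,
#' filtered by area bounds, then optionally by roundness
#' (`4 * pi * area / perimeter^2`) and by centroid distance to the nuclear
#' boundary (the rule for round FG-Nup accumulations close to the nuclear
#' envelope).
#'
#' @param image [channel_image()].
#' @param region_mask optional logical mask restricting the search.
#' @param intensity_threshold absolute intensity threshold.
#' @param min_area_um2,max_area_um2 area bounds in square micrometres.
#' @param min_roundness optional minimum roundness.
#' @param max_dist_to_envelope_um optional maximum centroid distance to the
#'   nucleus boundary, micrometres; requires `nucleus_mask`.
#' @param nucleus_mask logical nucleus mask for the envelope-distance rule.
#' @return a `puncta_set` data.frame (one row per retained punctum:
#'   `area_um2`, `row`, `col`, `mean_intensity`, `roundness`,
#'   `dist_to_envelope_um`) with the detection parameters stored in
#'   `attr(, "params")`.
#' @export
detect_puncta <- function(image, region_mask = NULL, intensity_threshold,
                          min_area_um2, max_area_um2,
                          min_roundness = NULL, max_dist_to_envelope_um = NULL,
                          nucleus_mask = NULL) {
  image <- .as_channel(image, pixel_size = 1)
  if (min_area_um2 >= max_area_um2)
    stop("min_area_um2 must be smaller than max_area_um2")
  if (!is.null(max_dist_to_envelope_um) && is.null(nucleus_mask))
    stop("the envelope-distance filter requires nucleus_mask")
  ps <- image$pixel_size
  fg <- image$pixels > intensity_threshold
  if (!is.null(region_mask)) fg <- fg & region_mask
  empty <- data.frame(area_um2 = numeric(0), row = numeric(0), col = numeric(0),
                      mean_intensity = numeric(0), roundness = numeric(0),
                      dist_to_envelope_um = numeric(0))
  params <- list(intensity_threshold = intensity_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_roundness = min_roundness,
                 max_dist_to_envelope_um = max_dist_to_envelope_um)
  if (!any(fg))
    return(structure(empty, params = params, class = c("puncta_set", "data.frame")))
  lab <- .ebi_mat(EBImage::bwlabel(EBImage::Image(fg * 1)))
  d_nuc <- if (!is.null(nucleus_mask)) {
    boundary <- nucleus_mask & !erode_mask(nucleus_mask, 1)
    .dist_to_mask(boundary)
  } else NULL
  rows <- list()
  for (k in seq_len(max(lab))) {
    m <- lab == k
    area_px <- sum(m)
    area <- area_px * ps^2
    if (area < min_area_um2 || area > max_area_um2) next
    idx <- which(m, arr.ind = TRUE)
    ctr <- colMeans(idx)
    perim <- mask_perimeter(m, pixel_size = 1)
    roundness <- if (perim > 0) 4 * pi * area_px / perim^2 else 1
    if (!is.null(min_roundness) && roundness < min_roundness) next
    dist_um <- if (!is.null(d_nuc))
      d_nuc[round(ctr[1]), round(ctr[2])] * ps else NA_real_
    if (!is.null(max_dist_to_envelope_um) &&
        (is.na(dist_um) || dist_um > max_dist_to_envelope_um)) next
    rows[[length(rows) + 1L]] <- data.frame(
      area_um2 = area, row = ctr[1], col = ctr[2],
      mean_intensity = .masked_mean(image$pixels, m),
      roundness = roundness, dist_to_envelope_um = dist_um)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, params = params, class = c("puncta_set", "data.frame"))
}

#' Count detected puncta
#' @param puncta a `puncta_set`.
#' @return non-negative integer count.
#' @export
puncta_count <- function(puncta) nrow(puncta)

#' Summarize punctum sizes
#' @param puncta a `puncta_set`.
#' @return `list(count =, mean_area_um2 =)`; mean area is `NA` for an empty
#'   set.
#' @export
puncta_size_summary <- function(puncta) {
  list(count = nrow(puncta),
       mean_area_um2 = if (nrow(puncta) > 0) mean(puncta$area_um2) else NA_real_)
}

#' Match detected puncta to planted ground truth
#'
#' Greedy nearest-centroid matching within a distance budget; the standard
#' sensitivity / false-detection bookkeeping for validating a detector
#' against a generated scene.
#'
#' @param detected a `puncta_set`.
#' @param truth data.frame with `row`, `col` columns (planted centroids, px).
#' @param max_dist_px maximal centroid distance for a match.
#' @return `list(n_matched =, n_missed =, n_false =)`.
#' @export
match_puncta <- function(detected, truth, max_dist_px = 3) {
  if (nrow(truth) == 0)
    return(list(n_matched = 0L, n_missed = 0L, n_false = nrow(detected)))
  if (nrow(detected) == 0)
    return(list(n_matched = 0L, n_missed = nrow(truth), n_false = 0L))
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$row - truth$row[i])^2 + (detected$col - truth$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= max_dist_px^2) { used[j] <- TRUE; matched <- matched + 1L }
  }
  list(n_matched = matched, n_missed = nrow(truth) - matched,
       n_false = sum(!used))
}

#' Envelope intensity profile around the nuclear boundary
#'
#' Traces the nucleus boundary in a fixed orientation (starting at the
#' topmost-then-leftmost boundary pixel) and samples, at every boundary
#' pixel, the maximum ring intensity along the outward normal within the
#' ring width. Arc length accrues with corrected boundary-walk weights
#' scaled by the pixel size.
#'
#' @param image [channel_image()].
#' @param nucleus_mask simply-connected logical nucleus mask.
#' @param ring_width_um width of the sampling annulus, micrometres.
#' @return an `envelope_profile` list: `path` (boundary pixels), `arc_um`
#'   (strictly increasing arc positions), `intensity`, `perimeter_um`,
#'   `pixel_size`.
#' @export
envelope_profile <- function(image, nucleus_mask, ring_width_um = 1.3) {
  image <- .as_channel(image, pixel_size = 1)
  ps <- image$pixel_size
  if (.n_components(nucleus_mask) != 1L)
    stop("nucleus mask must be a single connected component")
  filled <- .ebi_mat(EBImage::fillHull(EBImage::Image(nucleus_mask * 1))) > 0
  if (!identical(which(filled), which(nucleus_mask)))
    stop("nucleus mask is multiply connected (contains holes)")
  w_px <- max(1L, um_to_px(ring_width_um, ps))
  annulus <- dilate_mask(nucleus_mask, w_px) & !nucleus_mask
  path <- trace_boundary(nucleus_mask)
  n <- nrow(path)
  steps <- boundary_step_lengths(path, ps, closed = TRUE)
  arc <- cumsum(c(0, steps[-n]))
  perimeter <- sum(steps)
  # outward normal per boundary point from the local tangent (neighbours
  # +/-2 along the closed path), oriented away from the mask centroid
  ctr <- colMeans(which(nucleus_mask, arr.ind = TRUE))
  i_prev <- ((seq_len(n) - 3L) %% n) + 1L
  i_next <- ((seq_len(n) + 1L) %% n) + 1L
  tg <- path[i_next, , drop = FALSE] - path[i_prev, , drop = FALSE]
  nrm <- cbind(-tg[, 2], tg[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  outward <- rowSums(nrm * (path - matrix(ctr, n, 2, byrow = TRUE)))
  nrm[outward < 0, ] <- -nrm[outward < 0, ]
  px <- image$pixels
  nr <- nrow(px); ncl <- ncol(px)
  offs <- seq(0.5, w_px, by = 0.5)
  intensity <- rep(-Inf, n)
  for (o in offs) {
    rr <- round(path[, 1] + nrm[, 1] * o)
    cc <- round(path[, 2] + nrm[, 2] * o)
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncl
    ii <- which(ok)
    lin <- (cc[ii] - 1L) * nr + rr[ii]
    in_ring <- annulus[lin]
    sel <- ii[in_ring]
    if (length(sel))
      intensity[sel] <- pmax(intensity[sel], px[(cc[sel] - 1L) * nr + rr[sel]])
  }
  intensity[!is.finite(intensity)] <- 0
  structure(list(path = path, arc_um = arc, intensity = intensity,
                 step_um = steps, perimeter_um = perimeter, pixel_size = ps),
            class = "envelope_profile")
}

#' Nuclear-envelope continuity index
#'
#' Binarizes an envelope profile at a signal threshold; the index is the
#' total supra-threshold arc length divided by the nuclear perimeter (1 =
#' unbroken rim, lower = more discontinuity). Fragments are maximal
#' supra-threshold runs and gaps maximal sub-threshold runs, merged
#' circularly across the trace start.
#'
#' @param profile an [envelope_profile()].
#' @param signal_threshold intensity threshold separating envelope signal
#'   from background.
#' @return `list(index, fragment_count, gap_count)`; an all-sub-threshold
#'   profile yields index 0 with 0 fragments and 1 gap.
#' @export
continuity_index <- function(profile, signal_threshold) {
  stopifnot(inherits(profile, "envelope_profile"))
  supra <- profile$intensity > signal_threshold
  n <- length(supra)
  idx <- sum(profile$step_um[supra]) / profile$perimeter_um
  r <- rle(supra)
  frag <- sum(r$values)
  gaps <- sum(!r$values)
  if (length(r$values) > 1 && r$values[1] == r$values[length(r$values)]) {
    if (r$values[1]) frag <- frag - 1L else gaps <- gaps - 1L
  }
  list(index = idx, fragment_count = as.integer(frag),
       gap_count = as.integer(gaps))
}

#' Default continuity threshold from a ring region
#'
#' `background + 0.5 * (median ring intensity - background)`: the halfway
#' point between background and the typical envelope signal. A heuristic
#' default; pass an explicit threshold when the planted or calibrated
#' levels are known.
#'
#' @param image [channel_image()].
#' @param ring_mask annulus mask to take the median over.
#' @param background background intensity.
#' @return threshold intensity.
#' @export
continuity_threshold <- function(image, ring_mask, background = 0) {
  image <- .as_channel(image, pixel_size = 1)
  background + 0.5 * (stats::median(image$pixels[ring_mask]) - background)
}

#' Circularity of a mask
#'
#' `4 * pi * area / perimeter^2`, with the area from the pixel count and
#' the perimeter from the same weighted boundary walk used for envelope arc
#' length; 1 for a circle, `pi / 4` for a square.
#'
#' @param mask logical matrix, single connected component.
#' @param pixel_size micrometres per pixel (cancels in the ratio).
#' @return circularity in `(0, ~1]`.
#' @export
circularity <- function(mask, pixel_size = 1) {
  if (!any(mask)) stop("mask is empty")
  if (.n_components(mask) != 1L)
    stop("circularity requires a single connected component")
  area <- sum(mask) * pixel_size^2
  perim <- mask_perimeter(mask, pixel_size)
  4 * pi * area / perim^2
}

#' Thresholded-mask colocalization ratio
#'
#' Area of the intersection of two thresholded channel masks divided by the
#' area of the reference (first) channel's mask, per image. This is the
#' overlap-area statistic (e.g. Iba1/CD68 vs XPO1), not a
#' correlation-based colocalization measure.
#'
#' @param chanA reference [channel_image()] (denominator mask).
#' @param chanB second channel.
#' @param thresholdA,thresholdB absolute intensity thresholds.
#' @param region optional logical mask restricting the comparison.
#' @return ratio in `[0, 1]`, or `NA` with a warning when the reference
#'   mask is empty.
#' @export
colocalization_ratio <- function(chanA, chanB, thresholdA, thresholdB,
                                 region = NULL) {
  chanA <- .as_channel(chanA, pixel_size = 1)
  chanB <- .as_channel(chanB, pixel_size = 1)
  stopifnot(all(dim(chanA$pixels) == dim(chanB$pixels)))
  mA <- chanA$pixels > thresholdA
  mB <- chanB$pixels > thresholdB
  if (!is.null(region)) { mA <- mA & region; mB <- mB & region }
  nA <- sum(mA)
  if (nA == 0) {
    warning("reference channel has no supra-threshold pixels; ratio undefined")
    return(NA_real_)
  }
  sum(mA & mB) / nA
}

#' Intensity profile along a line
#'
#' Bilinear interpolation of one or more channels at equally spaced points
#' between two pixel coordinates, with distances in micrometres; the tool
#' behind line-scan colocalization plots.
#'
#' @param images a [channel_image()] or named list of them (equal shapes
#'   and pixel sizes).
#' @param p0,p1 `c(row, col)` endpoints (1-based, inside the image).
#' @param n_samples number of sample points.
#' @return data.frame with `distance_um` and one intensity column per
#'   channel.
#' @export
line_profile <- function(images, p0, p1, n_samples = 100) {
  if (inherits(images, "channel_image")) images <- list(images)
  if (is.null(names(images)) || any(names(images) == ""))
    names(images) <- vapply(images, function(im) im$channel, "")
  if (all(p0 == p1)) stop("line endpoints must differ")
  ps <- images[[1]]$pixel_size
  dm <- dim(images[[1]]$pixels)
  for (im in images) stopifnot(all(dim(im$pixels) == dm), im$pixel_size == ps)
  if (any(c(p0, p1) < 1) || any(c(p0[1], p1[1]) > dm[1]) ||
      any(c(p0[2], p1[2]) > dm[2]))
    stop("line endpoints must lie inside the image")
  tfrac <- seq(0, 1, length.out = n_samples)
  rr <- p0[1] + tfrac * (p1[1] - p0[1])
  cc <- p0[2] + tfrac * (p1[2] - p0[2])
  out <- data.frame(distance_um = tfrac * sqrt(sum((p1 - p0)^2)) * ps)
  for (nm in names(images)) {
    px <- images[[nm]]$pixels
    r0 <- pmin(pmax(floor(rr), 1), dm[1] - 1); c0 <- pmin(pmax(floor(cc), 1), dm[2] - 1)
    fr <- rr - r0; fc <- cc - c0
    v <- px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      px[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      px[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      px[cbind(r0 + 1, c0 + 1)] * fr * fc
    out[[nm]] <- v
  }
  out
}

#' Normalize measurements to the control-group mean per experiment
#'
#' Divides every value by the mean of the control-group values within its
#' experiment, so the control mean is 1 in each independent experiment.
#'
#' @param table data.frame with at least `value`, a group column and an
#'   experiment column.
#' @param control_group control level of the group column.
#' @param group,experiment column names.
#' @return the table with `value` rescaled.
#' @export
normalize_to_control <- function(table, control_group, group = "group",
                                 experiment = "experiment") {
  stopifnot(is.data.frame(table), "value" %in% names(table),
            group %in% names(table), experiment %in% names(table))
  for (e in unique(table[[experiment]])) {
    sel <- table[[experiment]] == e
    ctrl <- sel & table[[group]] == control_group
    if (!any(ctrl))
      stop(sprintf("experiment '%s' contains no '%s' control cells",
                   as.character(e), as.character(control_group)))
    table$value[sel] <- table$value[sel] / mean(table$value[ctrl])
  }
  table
}
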