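#' Specify one marker channel of a synthetic scene
#'
#' Each field is the ground-truth counterpart of a measured quantity: the
#' planted cytosol-to-nucleus ratio is `cytosol_level / nucleus_level`, the
#' envelope ring carries `ring_level` over a `ring_width_um` annulus with a
#' `gap_fraction` of the nuclear perimeter left dark, puncta are disks of
#' known count/size/intensity, and `overlap_with` plants an exact
#' mask-overlap fraction against an earlier channel.
#'
#' @param name channel label.
#' @param nucleus_level,cytosol_level mean intensities added over the
#'   nucleus / cytosol (arbitrary units above background).
#' @param ring_level intensity added on the (gapped) envelope ring.
#' @param ring_width_um annulus width in micrometres (default 1.3, the
#'   laminar-ring dilation used throughout).
#' @param gap_fraction fraction of the nuclear perimeter (arc length) with
#'   no ring signal, in `[0, 1]`.
#' @param n_gaps number of contiguous gap arcs; `NULL` draws 1-3 per cell.
#' @param n_puncta planted puncta per cell (in the cytosol).
#' @param punctum_radius_um punctum radius in micrometres.
#' @param punctum_level punctum intensity (added).
#' @param puncta_near_envelope_um if set, puncta centres are placed within
#'   this distance of the nuclear boundary.
#' @param overlap_with `list(channel =, fraction =, level =)`: plant a
#'   foreground mask overlapping the named earlier channel's foreground by
#'   exactly `fraction` of that channel's area.
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(name, nucleus_level = 0, cytosol_level = 0,
                        ring_level = 0, ring_width_um = 1.3,
                        gap_fraction = 0, n_gaps = NULL,
                        n_puncta = 0, punctum_radius_um = 0.5,
                        punctum_level = 0, puncta_near_envelope_um = NULL,
                        overlap_with = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  lv <- c(nucleus_level, cytosol_level, ring_level, punctum_level)
  if (any(lv < 0)) stop("marker intensities must be >= 0")
  if (gap_fraction < 0 || gap_fraction > 1) stop("gap_fraction must be in [0, 1]")
  if (gap_fraction > 0.85) stop("gap_fraction > 0.85 leaves no measurable fragment")
  if (!is.null(n_gaps)) stopifnot(n_gaps >= 1, n_gaps <= 6)
  if (ring_width_um <= 0) stop("ring_width_um must be > 0")
  if (!is.null(overlap_with)) {
    stopifnot(is.list(overlap_with), !is.null(overlap_with$channel),
              !is.null(overlap_with$fraction))
    if (overlap_with$fraction < 0 || overlap_with$fraction > 1)
      stop("overlap fraction must be in [0, 1]")
    if (is.null(overlap_with$level)) overlap_with$level <- 200
  }
  structure(list(name = name, nucleus_level = nucleus_level,
                 cytosol_level = cytosol_level, ring_level = ring_level,
                 ring_width_um = ring_width_um, gap_fraction = gap_fraction,
                 n_gaps = n_gaps, n_puncta = n_puncta,
                 punctum_radius_um = punctum_radius_um,
                 punctum_level = punctum_level,
                 puncta_near_envelope_um = puncta_near_envelope_um,
                 overlap_with = overlap_with),
            class = "marker_spec")
}

#' Specify a synthetic multi-channel microscopy scene
#'
#' Defaults emulate a confocal field of spinal motor neurons at high
#' magnification: 0.2 um/px sampling, nuclei of ~5 um radius inside somata
#' of ~9 um radius, mildly elliptical nuclei (axis ratio at most
#' `axis_ratio_max`, shape largely preserved), a DNA counterstain, and
#' Poisson shot noise plus Gaussian read noise when enabled.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_cells number of cells to place (non-overlapping; placement
#'   fails with an informative error when too dense).
#' @param nucleus_radius `c(mean, sd)` nuclear equivalent radius, um.
#' @param cell_radius `c(mean, sd)` cell equivalent radius, um.
#' @param background_level constant background intensity.
#' @param dna_level DNA-stain intensity added over nuclei.
#' @param markers list of [marker_spec()] objects.
#' @param noise `list(gaussian_sd =, poisson =)`; Poisson noise is applied
#'   to signal + background first, then additive Gaussian read noise.
#' @param axis_ratio_max maximal nuclear axis ratio (>= 1).
#' @param seed integer seed; fully determines the scene.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(512, 512), pixel_size = 0.2,
                       n_cells = 6,
                       nucleus_radius = c(5, 0.4), cell_radius = c(9, 0.8),
                       background_level = 20, dna_level = 400,
                       markers = list(),
                       noise = list(gaussian_sd = 0, poisson = FALSE),
                       axis_ratio_max = 1.3, seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            pixel_size > 0, n_cells >= 1,
            length(nucleus_radius) == 2, length(cell_radius) == 2,
            nucleus_radius[1] > 0, cell_radius[1] > 0,
            background_level >= 0, dna_level >= 0,
            axis_ratio_max >= 1, axis_ratio_max <= 1.5)
  if (nucleus_radius[1] >= cell_radius[1])
    stop("mean nucleus radius must be smaller than mean cell radius")
  if (is.null(noise$gaussian_sd)) noise$gaussian_sd <- 0
  if (is.null(noise$poisson)) noise$poisson <- FALSE
  stopifnot(noise$gaussian_sd >= 0)
  for (m in markers) if (!inherits(m, "marker_spec"))
    stop("markers must be a list of marker_spec objects")
  nm <- vapply(markers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate marker names")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, n_cells = as.integer(n_cells),
                 nucleus_radius = nucleus_radius, cell_radius = cell_radius,
                 background_level = background_level, dna_level = dna_level,
                 markers = markers, noise = noise,
                 axis_ratio_max = axis_ratio_max, seed = as.integer(seed)),
            class = "scene_spec")
}

# Normalized arc-length fraction s(t) along an ellipse with semi-axes a, b,
# as a lookup table over the parametric angle t in [0, 2*pi).
.ellipse_arc_table <- function(a, b, n = 2048L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  sp <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  s <- cumsum(c(0, (sp[-1] + sp[-length(sp)]) / 2 * diff(t)))[seq_len(n + 1L)]
  list(t = t, s = s / s[n + 1L])
}

# Draw gap arcs: returns a k x 2 matrix of [start, end) intervals on the
# normalized arc-length circle [0, 1). Gaps are disjoint with margins so
# fragment and gap counts are unambiguous on the raster.
.draw_gap_arcs <- function(gap_fraction, n_gaps) {
  if (gap_fraction <= 0) return(matrix(numeric(0), ncol = 2))
  k <- if (is.null(n_gaps)) sample(1:3, 1) else as.integer(n_gaps)
  sector <- 1 / k
  for (try in 1:50) {
    p <- runif(k) + 0.5
    len <- gap_fraction * p / sum(p)
    if (all(len <= sector - 0.06)) break
    if (try == 50) len <- rep(gap_fraction / k, k)  # even split always fits
  }
  rot <- runif(1)
  centers <- rot + (seq_len(k) - 0.5) * sector +
    runif(k, -1, 1) * pmax(0, (sector - len) / 2 - 0.02)
  cbind(start = (centers - len / 2) %% 1, end = (centers + len / 2) %% 1)
}

.in_arcs <- function(s, arcs) {
  if (nrow(arcs) == 0) return(rep(FALSE, length(s)))
  hit <- rep(FALSE, length(s))
  for (i in seq_len(nrow(arcs))) {
    a <- arcs[i, 1]; b <- arcs[i, 2]
    hit <- hit | if (a <= b) (s >= a & s < b) else (s >= a | s < b)
  }
  hit
}

#' Generate a synthetic multi-channel scene with ground truth
#'
#' Rasterizes non-overlapping cells (elliptical nucleus inside a concentric
#' elliptical soma), renders every marker channel plus a DNA channel, then
#' applies the configured noise. The same seed yields bit-identical pixels
#' and ground truth.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `scene` with elements `channels` (named list of
#'   [channel_image()]s, including `"DNA"`), `ground_truth` (cells table,
#'   per-cell masks, planted C/N ratios, gap arcs, puncta and overlap
#'   fractions) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  ps <- spec$pixel_size
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]

  ring_widths <- vapply(spec$markers, function(m)
    if (m$ring_level > 0) m$ring_width_um else 0, 0)
  margin_px <- max(0, if (length(ring_widths)) um_to_px(max(ring_widths), ps) else 0) + 2

  ## ---- place cells (rejection sampling) ----
  cells <- list()
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in 1:300) {
      r_n <- max(2.5 * ps, rnorm(1, spec$nucleus_radius[1], spec$nucleus_radius[2]))
      # keep a measurable cytosolic annulus around every nucleus
      min_gap <- max(if (length(ring_widths)) max(ring_widths) + 0.5 else 0, 2.5)
      r_c <- max(r_n + min_gap,
                 rnorm(1, spec$cell_radius[1], spec$cell_radius[2]))
      q <- runif(1, 1, spec$axis_ratio_max)
      theta <- runif(1, 0, pi)
      a_c <- r_c / ps * sqrt(q)
      pad <- a_c + margin_px + 1
      if (2 * pad + 2 >= min(nr, nc)) next  # this draw cannot fit the field
      ctr <- c(runif(1, 1 + pad, nr - pad), runif(1, 1 + pad, nc - pad))
      ok <- TRUE
      for (cl in cells) {
        if (sqrt(sum((ctr - cl$center)^2)) < (r_c + cl$r_cell) / ps * sqrt(spec$axis_ratio_max) + 3) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        cells[[i]] <- list(cell_id = i, center = ctr, r_nuc = r_n, r_cell = r_c,
                           q = q, theta = theta)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(paste0("could not place %d non-overlapping cells of mean radius ",
                          "%.1f um in a %d x %d px field (density too high)"),
                   spec$n_cells, spec$cell_radius[1], nr, nc))
  }

  ## ---- masks ----
  shape <- c(nr, nc)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    a_n <- cl$r_nuc / ps * sqrt(cl$q); b_n <- cl$r_nuc / ps / sqrt(cl$q)
    a_c <- cl$r_cell / ps * sqrt(cl$q); b_c <- cl$r_cell / ps / sqrt(cl$q)
    cells[[i]]$axes_nuc <- c(a_n, b_n)
    cells[[i]]$nucleus <- rasterize_ellipse(shape, cl$center, a_n, b_n, cl$theta)
    cells[[i]]$cell <- rasterize_ellipse(shape, cl$center, a_c, b_c, cl$theta)
  }

  gt_cells <- do.call(rbind, lapply(cells, function(cl)
    data.frame(cell_id = cl$cell_id, row = cl$center[1], col = cl$center[2],
               nucleus_radius_um = cl$r_nuc, cell_radius_um = cl$r_cell,
               axis_ratio = cl$q, theta = cl$theta)))
  gt_masks <- lapply(cells, function(cl)
    list(nucleus = cl$nucleus, cell = cl$cell, rings = list()))
  names(gt_masks) <- paste0("cell", vapply(cells, `[[`, 0, "cell_id"))
  gt_cn <- gt_gaps <- gt_puncta <- gt_overlap <- NULL

  ## ---- render channels ----
  channels <- list()
  base <- matrix(spec$background_level, nr, nc)
  dna <- base
  for (cl in cells) dna[cl$nucleus] <- dna[cl$nucleus] + spec$dna_level
  channels[["DNA"]] <- dna

  deferred <- Filter(function(m) !is.null(m$overlap_with), spec$markers)
  direct <- Filter(function(m) is.null(m$overlap_with), spec$markers)

  for (m in direct) {
    img <- base
    for (ci in seq_along(cells)) {
      cl <- cells[[ci]]
      cyt <- cl$cell & !cl$nucleus
      if (m$nucleus_level > 0) img[cl$nucleus] <- img[cl$nucleus] + m$nucleus_level
      if (m$cytosol_level > 0) img[cyt] <- img[cyt] + m$cytosol_level
      if (m$nucleus_level > 0)
        gt_cn <- rbind(gt_cn, data.frame(
          cell_id = cl$cell_id, channel = m$name,
          cn = m$cytosol_level / m$nucleus_level))
      if (m$ring_level > 0) {
        w_px <- um_to_px(m$ring_width_um, ps)
        annulus <- dilate_mask(cl$nucleus, w_px) & !cl$nucleus
        arcs <- .draw_gap_arcs(m$gap_fraction, m$n_gaps)
        ring_sig <- annulus
        if (nrow(arcs) > 0) {
          rc <- which(annulus, arr.ind = TRUE)
          dxy <- cbind(rc[, 2] - cl$center[2], rc[, 1] - cl$center[1])
          u <- dxy[, 1] * cos(cl$theta) + dxy[, 2] * sin(cl$theta)
          v <- -dxy[, 1] * sin(cl$theta) + dxy[, 2] * cos(cl$theta)
          tpar <- atan2(v / cl$axes_nuc[2], u / cl$axes_nuc[1]) %% (2 * pi)
          tab <- .ellipse_arc_table(cl$axes_nuc[1], cl$axes_nuc[2])
          s <- stats::approx(tab$t, tab$s, xout = tpar, rule = 2)$y
          drop <- .in_arcs(s, arcs)
          ring_sig[rc[drop, , drop = FALSE]] <- FALSE
        }
        img[ring_sig] <- img[ring_sig] + m$ring_level
        gt_masks[[ci]]$rings[[m$name]] <-
          list(annulus = annulus, signal = ring_sig)
        gt_gaps <- rbind(gt_gaps, data.frame(
          cell_id = cl$cell_id, channel = m$name,
          gap_fraction = m$gap_fraction, n_gaps = nrow(arcs)))
      }
      if (m$n_puncta > 0) {
        r_p <- max(1L, um_to_px(m$punctum_radius_um, ps))
        region <- erode_mask(cyt, r_p + 1L)
        if (!is.null(m$puncta_near_envelope_um)) {
          d <- .dist_to_mask(cl$nucleus)
          region <- region & (d <= m$puncta_near_envelope_um / ps)
        }
        cand <- which(region, arr.ind = TRUE)
        if (nrow(cand) == 0)
          stop(sprintf("cell %d: cytosol too small to hold puncta of radius %d px",
                       cl$cell_id, r_p))
        centers <- matrix(numeric(0), ncol = 2)
        guard2 <- (2 * r_p + 3)^2
        for (k in seq_len(m$n_puncta)) {
          ok <- FALSE
          for (try in 1:200) {
            p <- cand[sample.int(nrow(cand), 1), ]
            if (nrow(centers) == 0 ||
                all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 > guard2)) {
              centers <- rbind(centers, p); ok <- TRUE; break
            }
          }
          if (!ok)
            stop(sprintf("could not place %d puncta of radius %d px in cell %d (cytosol too small)",
                         m$n_puncta, r_p, cl$cell_id))
        }
        for (k in seq_len(nrow(centers)))
          img <- draw_disk(img, centers[k, ], r_p, m$punctum_level)
        gt_puncta <- rbind(gt_puncta, data.frame(
          cell_id = cl$cell_id, channel = m$name,
          row = centers[, 1], col = centers[, 2], radius_px = r_p))
      }
    }
    channels[[m$name]] <- img
  }

  any_cell <- Reduce(`|`, lapply(cells, `[[`, "cell"))
  for (m in deferred) {
    ref <- channels[[m$overlap_with$channel]]
    if (is.null(ref))
      stop(sprintf("overlap_with references unknown channel '%s'",
                   m$overlap_with$channel))
    fgA <- which(ref > spec$background_level + 1e-9)
    if (length(fgA) == 0) stop("overlap reference channel has no foreground")
    f <- m$overlap_with$fraction
    k <- round(f * length(fgA))
    img <- base
    bsel <- fgA[seq_len(k)]
    img[bsel] <- img[bsel] + m$overlap_with$level
    n_extra <- round((1 - f) * length(fgA))
    if (n_extra > 0) {
      bg_ok <- which(!any_cell & ref <= spec$background_level + 1e-9)
      extra <- bg_ok[seq_len(min(n_extra, length(bg_ok)))]
      img[extra] <- img[extra] + m$overlap_with$level
    }
    channels[[m$name]] <- img
    gt_overlap <- rbind(gt_overlap, data.frame(
      channel = m$name, reference = m$overlap_with$channel,
      fraction = f, fraction_realized = k / length(fgA)))
  }

  ## ---- noise ----
  for (nm in names(channels)) {
    px <- channels[[nm]]
    if (isTRUE(spec$noise$poisson)) px[] <- stats::rpois(length(px), lambda = px)
    if (spec$noise$gaussian_sd > 0)
      px[] <- px + stats::rnorm(length(px), 0, spec$noise$gaussian_sd)
    px[px < 0] <- 0
    channels[[nm]] <- channel_image(px, ps, nm)
  }

  structure(list(channels = channels,
                 ground_truth = list(cells = gt_cells, masks = gt_masks,
                                     cn = gt_cn, gaps = gt_gaps,
                                     puncta = gt_puncta, overlap = gt_overlap),
                 spec = spec),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d x %d px, %d cells, channels: %s\n",
              x$spec$image_shape[1], x$spec$image_shape[2],
              nrow(x$ground_truth$cells),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Specify a clustered cohort design
#'
#' Groups of clusters (animals, cell lines or independent experiments) of
#' cells with cluster-level random intercepts; the test-bed for the
#' cluster-robust rank statistics. Defaults match the calibration design
#' used throughout: 3 groups x 5 clusters x 40 cells at intra-cluster
#' correlation 0.3.
#'
#' @param n_groups number of groups.
#' @param group_effects additive shifts on the latent scale, one per group.
#' @param clusters_per_group clusters per group (>= 2; variance is not
#'   estimable otherwise).
#' @param cells_per_cluster cells per cluster.
#' @param cluster_sd SD of cluster random intercepts.
#' @param cell_sd residual SD.
#' @param distribution `"gaussian"` or `"lognormal"` (the latter
#'   exponentiates the latent value).
#' @param baseline latent grand intercept.
#' @param seed integer seed.
#' @return a `cohort_design` list; its implied intra-cluster correlation is
#'   `cluster_sd^2 / (cluster_sd^2 + cell_sd^2)`.
#' @export
cohort_design <- function(n_groups = 3, group_effects = rep(0, n_groups),
                          clusters_per_group = 5, cells_per_cluster = 40,
                          cluster_sd = sqrt(0.3 / 0.7), cell_sd = 1,
                          distribution = c("gaussian", "lognormal"),
                          baseline = 0, seed = 1) {
  distribution <- match.arg(distribution)
  stopifnot(n_groups >= 1, length(group_effects) == n_groups,
            cells_per_cluster >= 1, cluster_sd >= 0, cell_sd > 0)
  if (clusters_per_group < 2)
    stop("clusters_per_group must be >= 2 (cluster variance not estimable)")
  icc <- cluster_sd^2 / (cluster_sd^2 + cell_sd^2)
  structure(list(n_groups = as.integer(n_groups), group_effects = group_effects,
                 clusters_per_group = as.integer(clusters_per_group),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 cluster_sd = cluster_sd, cell_sd = cell_sd, icc = icc,
                 distribution = distribution, baseline = baseline,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a clustered cohort measurement table
#'
#' @param design a [cohort_design()].
#' @return data.frame with columns `group` (factor), `cluster` (unique
#'   across groups), `cell`, `value`; one row per cell, with
#'   `value = baseline + group effect + cluster intercept + residual`
#'   (exponentiated under the lognormal option).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  rows <- vector("list", design$n_groups * design$clusters_per_group)
  idx <- 0L
  for (g in seq_len(design$n_groups)) {
    for (cl in seq_len(design$clusters_per_group)) {
      b <- stats::rnorm(1, 0, design$cluster_sd)
      v <- design$baseline + design$group_effects[g] + b +
        stats::rnorm(design$cells_per_cluster, 0, design$cell_sd)
      if (design$distribution == "lognormal") v <- exp(v)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        group = sprintf("g%d", g),
        cluster = sprintf("g%d_c%d", g, cl),
        cell = seq_len(design$cells_per_cluster),
        value = v)
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group)
  rownames(out) <- NULL
  out
}
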