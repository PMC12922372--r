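test_that("nucleus segmentation recovers ground-truth masks on clean scenes", {
  sc <- cn_scene(2, seed = 101, n_cells = 5)
  nuclei <- segment_nuclei(sc$channels$DNA)
  expect_length(nuclei, 5)
  for (i in 1:5) {
    best <- max(vapply(nuclei, function(n)
      jaccard(n, sc$ground_truth$masks[[i]]$nucleus), 0))
    expect_gte(best, 0.95)
  }
})

test_that("nucleus segmentation filters small components and rejects flat images", {
  img <- matrix(10, 64, 64)
  img <- draw_disk(img, c(32, 32), 3, 100)  # area 29 px = 1.16 um2 at 0.2 um/px
  ch <- channel_image(img, 0.2, "DNA")
  expect_length(segment_nuclei(ch, min_area_um2 = 10), 0)
  expect_length(segment_nuclei(ch, min_area_um2 = 1), 1)
  two <- draw_disk(img, c(15, 15), 5, 100)
  expect_length(segment_nuclei(channel_image(two, 0.2, "DNA"), min_area_um2 = 1), 2)
  expect_error(segment_nuclei(channel_image(matrix(5, 32, 32), 0.2, "DNA")),
               "no threshold")
})

test_that("cell segmentation pairs cells to nuclei and recovers true cell masks", {
  sc <- cn_scene(2, seed = 102, n_cells = 5)
  nuclei <- segment_nuclei(sc$channels$DNA)
  cells <- segment_cell(sc$channels$M, nuclei)
  expect_length(cells, 5)
  for (i in 1:5) {
    best <- max(vapply(cells, function(cl)
      jaccard(cl$cell_mask, sc$ground_truth$masks[[i]]$cell), 0))
    expect_gte(best, 0.9)
  }
  for (cl in cells) expect_false(any(cl$nucleus_mask & !cl$cell_mask))
})

test_that("a marker with no cytoplasm yields cell == nucleus with a warning", {
  sc <- cn_scene(2, seed = 103, n_cells = 3)
  nuclei <- segment_nuclei(sc$channels$DNA)
  w <- capture_warnings(cells <- segment_cell(sc$channels$DNA, nuclei))
  expect_match(w, "cytosol", all = TRUE)
  expect_length(w, 3)
  for (cl in cells) {
    expect_identical(cl$cell_mask, cl$nucleus_mask)
    expect_false(any(cl$cytosol_mask))
  }
})

test_that("touching cells split by the nearest-nucleus partition", {
  # one foreground blob containing two nuclei
  img <- matrix(0, 60, 100)
  img[20:40, 20:80] <- 100
  n1 <- rasterize_ellipse(c(60, 100), c(30, 35), 6, 6)
  n2 <- rasterize_ellipse(c(60, 100), c(30, 65), 6, 6)
  cells <- segment_cell(channel_image(img, 0.2, "M"), list(n1, n2),
                        method = "fixed", value = 50)
  expect_length(cells, 2)
  expect_false(any(cells[[1]]$cell_mask & cells[[2]]$cell_mask))
  blob <- img > 50
  expect_identical(cells[[1]]$cell_mask | cells[[2]]$cell_mask, blob | n1 | n2)
  # brute-force nearest-nucleus labelling agrees inside the blob
  idx <- which(blob & !n1 & !n2, arr.ind = TRUE)
  p1 <- which(n1, arr.ind = TRUE); p2 <- which(n2, arr.ind = TRUE)
  for (k in sample(nrow(idx), 50)) {
    d1 <- min((p1[, 1] - idx[k, 1])^2 + (p1[, 2] - idx[k, 2])^2)
    d2 <- min((p2[, 1] - idx[k, 1])^2 + (p2[, 2] - idx[k, 2])^2)
    if (abs(sqrt(d1) - sqrt(d2)) > 1.5) {  # skip the ambiguous midline
      owner <- if (d1 < d2) 1 else 2
      expect_true(cells[[owner]]$cell_mask[idx[k, 1], idx[k, 2]])
    }
  }
})

test_that("make_ring matches Euclidean-distance enumeration and the 1.3 um default", {
  nuc <- rasterize_ellipse(c(41, 41), c(21, 21), 10, 10)
  ring <- make_ring(nuc, outer_offset_um = 1.3, pixel_size = 0.325)
  # 1.3 / 0.325 = 4 px: brute-force distance-to-mask enumeration
  bf <- bf_dilate(nuc, 4) & !nuc
  expect_identical(which(ring), which(bf))
  # ring area identity: |dilate_outer| - |dilate_inner|
  outer <- dilate_mask(nuc, 4)
  expect_identical(sum(ring), sum(outer) - sum(nuc))
  expect_error(make_ring(nuc, 1.3, 1.3, 0.325), "exceed")
  expect_error(make_ring(nuc, 0.1, 0, 0.325), "resolvable")
})

test_that("rings are nested-monotone in the outer offset", {
  nuc <- rasterize_ellipse(c(51, 51), c(26, 26), 8, 6, 0.4)
  prev <- 0
  for (outer in c(0.5, 1.0, 1.5, 2.0)) {
    ring <- make_ring(nuc, outer, 0, pixel_size = 0.25)
    expect_gte(sum(ring), prev)
    prev <- sum(ring)
    expect_false(any(ring & nuc))
  }
})

test_that("perinuclear band delegates to make_ring and excludes the nucleus", {
  nuc <- rasterize_ellipse(c(41, 41), c(21, 21), 8, 8)
  band <- perinuclear_band(nuc, 1.0, pixel_size = 0.25)
  expect_identical(band, make_ring(nuc, 1.0, 0, 0.25))
  expect_false(any(band & nuc))
  # band width in px = round(width / pixel_size): max distance from nucleus
  d <- round(sqrt(max(apply(which(band, arr.ind = TRUE), 1, function(p)
    min((which(nuc, arr.ind = TRUE)[, 1] - p[1])^2 +
        (which(nuc, arr.ind = TRUE)[, 2] - p[2])^2)))))
  expect_equal(d, 4)
})

test_that("background estimation matches planted levels and sampling bounds", {
  flat <- channel_image(matrix(7, 50, 50), 0.2, "x")
  mask <- rasterize_ellipse(c(50, 50), c(25, 25), 8, 8)
  expect_equal(as.numeric(estimate_background(flat, list(mask))), 7)
  expect_identical(attr(estimate_background(flat, list(mask)), "statistic"), "median")
  sc <- cn_scene(2, seed = 104, n_cells = 3)
  bg <- estimate_background(sc$channels$M, lapply(gt_cells(sc), `[[`, "cell_mask"))
  expect_equal(as.numeric(bg), sc$spec$background_level)
  # Gaussian noise sd sigma: mean-background estimate within 3 sigma / sqrt(n)
  set.seed(5)
  noisy <- channel_image(pmax(matrix(rnorm(2500, 50, 4), 50, 50), 0), 0.2, "x")
  est <- estimate_background(noisy, list(mask), stat = "mean")
  expect_lt(abs(as.numeric(est) - 50), 3 * 4 / sqrt(attr(est, "n_pixels")) + 0.1)
  full <- matrix(TRUE, 50, 50)
  expect_error(estimate_background(flat, list(full)), "manual background")
})

test_that("segmented cells enforce the compartment algebra", {
  nuc <- rasterize_ellipse(c(30, 30), c(15, 15), 5, 5)
  cellm <- rasterize_ellipse(c(30, 30), c(15, 15), 10, 10)
  sc <- segmented_cell(1, nuc, cellm)
  expect_identical(sc$cytosol_mask, cellm & !nuc)
  expect_error(segmented_cell(1, cellm, nuc), "contained")
})
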