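make_cell <- function(shape = c(40, 40), ctr = c(20, 20), rn = 6, rc = 12) {
  segmented_cell(1, rasterize_ellipse(shape, ctr, rn, rn),
                 rasterize_ellipse(shape, ctr, rc, rc))
}

test_that("C/N and N/C ratios follow hand pixel arithmetic and are reciprocal", {
  cell <- make_cell()
  uni <- channel_image(matrix(5, 40, 40), 0.2, "u")
  expect_equal(cn_ratio(uni, cell, 0), 1.0)
  expect_equal(nc_gradient(uni, cell, 0), 1.0)
  img <- matrix(0, 40, 40)
  img[cell$nucleus_mask] <- 10
  img[cell$cytosol_mask] <- 20
  ch <- channel_image(img, 0.2, "m")
  expect_equal(cn_ratio(ch, cell, 0), 2.0)
  expect_equal(cn_ratio(ch, cell, 0) * nc_gradient(ch, cell, 0), 1.0)
  # with background subtraction
  expect_equal(cn_ratio(channel_image(img + 7, 0.2, "m"), cell, 7), 2.0)
})

test_that("undefined ratios are flagged NA, never clipped", {
  cell <- make_cell()
  img <- matrix(3, 40, 40)
  expect_warning(v <- cn_ratio(channel_image(img, 0.2, "m"), cell, 5), "undefined")
  expect_true(is.na(v))
})

test_that("laminar intensity equals the brute-force ring mean, bit-identically", {
  set.seed(20)
  img <- matrix(runif(1600, 0, 100), 40, 40)
  nuc <- rasterize_ellipse(c(40, 40), c(20, 20), 7, 7)
  ring <- make_ring(nuc, 1.3, 0, 0.2)
  ch <- channel_image(img, 0.2, "m")
  expect_identical(laminar_intensity(ch, ring, 10), bf_masked_mean(img, ring) - 10)
  expect_equal(laminar_intensity(channel_image(matrix(9, 40, 40), 0.2, "m"),
                                 ring, 2), 7)
  expect_error(laminar_intensity(ch, matrix(FALSE, 40, 40), 0), "empty")
})

test_that("laminar intensity recovers the planted ring level", {
  sp <- scene_spec(n_cells = 3, markers = list(
    marker_spec("Nup", ring_level = 250)), seed = 55)
  sc <- generate_scene(sp)
  for (i in 1:3) {
    nuc <- sc$ground_truth$masks[[i]]$nucleus
    ring <- make_ring(nuc, 1.3, 0, sc$spec$pixel_size)
    v <- laminar_intensity(sc$channels$Nup, ring, sc$spec$background_level)
    expect_equal(v, 250, tolerance = 0.05 * 250)
  }
})

test_that("envelope-to-nucleoplasm ratio recovers planted contrast", {
  uni <- channel_image(matrix(11, 40, 40), 0.2, "u")
  nuc <- rasterize_ellipse(c(40, 40), c(20, 20), 8, 8)
  expect_equal(envelope_to_nucleoplasm_ratio(uni, nuc), 1.0)
  sp <- scene_spec(n_cells = 3, background_level = 0, markers = list(
    marker_spec("Nup", nucleus_level = 100, ring_level = 200)), seed = 56)
  sc <- generate_scene(sp)
  for (i in 1:3) {
    r <- envelope_to_nucleoplasm_ratio(sc$channels$Nup,
                                       sc$ground_truth$masks[[i]]$nucleus)
    expect_equal(r, 2.0, tolerance = 0.05)
  }
  # pixel-enumeration oracle
  nucm <- sc$ground_truth$masks[[1]]$nucleus
  band <- dilate_mask(nucm, 1) & !nucm
  nucleo <- erode_mask(nucm, 2)
  expect_identical(envelope_to_nucleoplasm_ratio(sc$channels$Nup, nucm),
                   bf_masked_mean(sc$channels$Nup$pixels, band) /
                     bf_masked_mean(sc$channels$Nup$pixels, nucleo))
  tiny <- rasterize_ellipse(c(20, 20), c(10, 10), 1, 1)
  expect_warning(v <- envelope_to_nucleoplasm_ratio(uni, tiny), "erode")
  expect_true(is.na(v))
})

test_that("every mean-over-mask metric matches pixel enumeration on random masks", {
  set.seed(99)
  for (rep in 1:50) {
    img <- matrix(runif(1600, 0, 4095), 40, 40)
    mask <- random_blob(seed = rep)
    expect_identical(mean(img[mask]), bf_masked_mean(img, mask))
  }
})

test_that("puncta detection applies area, roundness and distance filters", {
  base <- matrix(10, 80, 80)
  ch0 <- channel_image(base, 0.2, "p")
  expect_equal(puncta_count(detect_puncta(ch0, intensity_threshold = 50,
                                          min_area_um2 = 0.2, max_area_um2 = 3)), 0)
  img <- base
  ctrs <- rbind(c(15, 15), c(15, 55), c(40, 30), c(60, 60), c(65, 20))
  for (k in 1:5) img <- draw_disk(img, ctrs[k, ], 3, 200)
  ch <- channel_image(img, 0.2, "p")
  p <- detect_puncta(ch, intensity_threshold = 100, min_area_um2 = 0.2,
                     max_area_um2 = 3)
  expect_equal(puncta_count(p), 5)
  expect_equal(match_puncta(p, data.frame(row = ctrs[, 1], col = ctrs[, 2]))$n_matched, 5)
  # too-small punctum excluded
  small <- draw_disk(base, c(40, 40), 1, 200)  # 5 px = 0.2 um2 > not; area 5*0.04
  psm <- detect_puncta(channel_image(small, 0.2, "p"), intensity_threshold = 100,
                       min_area_um2 = 0.5, max_area_um2 = 3)
  expect_equal(puncta_count(psm), 0)
  # low-roundness bar excluded
  bar <- base; bar[40, 20:60] <- 200
  pbar <- detect_puncta(channel_image(bar, 0.2, "p"), intensity_threshold = 100,
                        min_area_um2 = 0.05, max_area_um2 = 10,
                        min_roundness = 0.6)
  expect_equal(puncta_count(pbar), 0)
  # distance-to-envelope filter requires a nucleus and excludes far puncta
  nuc <- rasterize_ellipse(c(80, 80), c(15, 15), 8, 8)
  expect_error(detect_puncta(ch, intensity_threshold = 100, min_area_um2 = 0.2,
                             max_area_um2 = 3, max_dist_to_envelope_um = 2),
               "nucleus_mask")
  pnear <- detect_puncta(ch, intensity_threshold = 100, min_area_um2 = 0.2,
                         max_area_um2 = 3, max_dist_to_envelope_um = 2,
                         nucleus_mask = nuc)
  expect_lt(puncta_count(pnear), 5)
  expect_true(all(pnear$dist_to_envelope_um <= 2))
  expect_error(detect_puncta(ch, intensity_threshold = 1, min_area_um2 = 3,
                             max_area_um2 = 1), "smaller")
})

test_that("puncta summaries aggregate by enumeration", {
  empty <- detect_puncta(channel_image(matrix(0, 20, 20), 1, "p"),
                         intensity_threshold = 1, min_area_um2 = 0.5,
                         max_area_um2 = 5)
  s <- puncta_size_summary(empty)
  expect_equal(s$count, 0)
  expect_true(is.na(s$mean_area_um2))
  img <- matrix(0, 60, 60)
  img <- draw_disk(img, c(15, 15), 2, 10)
  img <- draw_disk(img, c(30, 30), 3, 10)
  img <- draw_disk(img, c(48, 48), 4, 10)
  p <- detect_puncta(channel_image(img, 1, "p"), intensity_threshold = 5,
                     min_area_um2 = 1, max_area_um2 = 100)
  s <- puncta_size_summary(p)
  expect_equal(s$count, 3)
  expect_equal(s$mean_area_um2, mean(p$area_um2))
  expect_equal(sort(p$area_um2), sort(c(sum(rasterize_ellipse(c(60, 60), c(15, 15), 2, 2)),
                                        sum(rasterize_ellipse(c(60, 60), c(30, 30), 3, 3)),
                                        sum(rasterize_ellipse(c(60, 60), c(48, 48), 4, 4)))))
})

test_that("envelope profiles are closed, increasing and level-faithful", {
  sp <- scene_spec(n_cells = 2, markers = list(
    marker_spec("Nup", ring_level = 300)), seed = 77)
  sc <- generate_scene(sp)
  nuc <- sc$ground_truth$masks[[1]]$nucleus
  prof <- envelope_profile(sc$channels$Nup, nuc, 1.3)
  expect_true(all(diff(prof$arc_um) > 0))
  expect_equal(prof$perimeter_um, sum(prof$step_um))
  # full ring: profile everywhere at the planted level
  expect_true(all(prof$intensity >= sc$spec$background_level + 300 - 1e-9))
  # perimeter of a rasterized disk within 5% of 2*pi*r
  disk <- rasterize_ellipse(c(120, 120), c(60, 60), 50, 50)
  expect_equal(mask_perimeter(disk), 2 * pi * 50, tolerance = 0.05)
  two <- rasterize_ellipse(c(120, 120), c(30, 30), 12, 12) |
    rasterize_ellipse(c(120, 120), c(90, 90), 12, 12)
  blank <- channel_image(matrix(0, 120, 120), 0.2, "x")
  expect_error(envelope_profile(blank, two, 1.3), "connected")
  holey <- disk; holey[55:65, 55:65] <- FALSE
  expect_error(envelope_profile(blank, holey, 1.3), "holes|connected")
})

test_that("continuity index tracks planted gaps, counts fragments circularly", {
  sp <- scene_spec(n_cells = 2, markers = list(
    marker_spec("Nup", ring_level = 300, gap_fraction = 0.25, n_gaps = 1)),
    seed = 78)
  sc <- generate_scene(sp)
  th <- sc$spec$background_level + 150
  for (i in 1:2) {
    prof <- envelope_profile(sc$channels$Nup, sc$ground_truth$masks[[i]]$nucleus, 1.3)
    ci <- continuity_index(prof, th)
    expect_equal(ci$index, 0.75, tolerance = 0.05)
    expect_equal(ci$fragment_count, 1L)
    expect_equal(ci$gap_count, 1L)
  }
  # synthetic profile edge cases
  fake <- structure(list(intensity = rep(10, 8), step_um = rep(1, 8),
                         perimeter_um = 8, arc_um = 0:7, pixel_size = 1),
                    class = "envelope_profile")
  expect_equal(continuity_index(fake, 5),
               list(index = 1, fragment_count = 1L, gap_count = 0L))
  expect_equal(continuity_index(fake, 20),
               list(index = 0, fragment_count = 0L, gap_count = 1L))
  # the run wrapping the start point is merged: T|FF|TT|F|TT circles to one
  fake$intensity <- c(10, 0, 0, 10, 10, 0, 10, 10)
  ci <- continuity_index(fake, 5)
  expect_equal(ci$index, 5 / 8)
  expect_equal(ci$fragment_count, 2L)
  expect_equal(ci$gap_count, 2L)
})

test_that("continuity index is monotone non-increasing in the planted gap fraction", {
  med <- vapply(c(0, 0.25, 0.5), function(g) {
    sp <- scene_spec(n_cells = 3, markers = list(
      marker_spec("Nup", ring_level = 300,
                  gap_fraction = g, n_gaps = if (g > 0) 2 else NULL)),
      seed = 79)
    sc <- generate_scene(sp)
    stats::median(vapply(1:3, function(i) {
      prof <- envelope_profile(sc$channels$Nup,
                               sc$ground_truth$masks[[i]]$nucleus, 1.3)
      continuity_index(prof, sc$spec$background_level + 150)$index
    }, 0))
  }, 0)
  expect_true(all(diff(med) < 0))
})

test_that("circularity: formula identities and rasterization accuracy", {
  # analytic identities: circle 4*pi*(pi r^2)/(2 pi r)^2 = 1; square = pi/4
  r <- 10; s <- 8
  expect_equal(4 * pi * (pi * r^2) / (2 * pi * r)^2, 1.0)
  expect_equal(4 * pi * s^2 / (4 * s)^2, pi / 4)
  disk <- rasterize_ellipse(c(121, 121), c(61, 61), 50, 50)
  expect_gte(circularity(disk), 0.95)
  expect_lte(circularity(disk), 1.05)
  # elongated shapes score lower
  ell <- rasterize_ellipse(c(121, 121), c(61, 61), 50, 20)
  expect_lt(circularity(ell), circularity(disk))
  expect_error(circularity(matrix(FALSE, 5, 5)), "empty")
})

test_that("colocalization ratio: identity, disjoint and rescaling invariance", {
  set.seed(30)
  a <- matrix(runif(1600, 0, 100), 40, 40)
  cha <- channel_image(a, 0.2, "a")
  expect_equal(colocalization_ratio(cha, cha, 50, 50), 1.0)
  b <- matrix(0, 40, 40); b[1:10, ] <- 100
  a2 <- matrix(0, 40, 40); a2[30:40, ] <- 100
  expect_equal(colocalization_ratio(channel_image(a2, 0.2, "a"),
                                    channel_image(b, 0.2, "b"), 50, 50), 0.0)
  # invariant under joint strictly monotone rescale of intensity + threshold
  r1 <- colocalization_ratio(cha, channel_image(a + 5, 0.2, "b"), 40, 60)
  f <- function(x) x^2 + 3 * x
  r2 <- colocalization_ratio(channel_image(f(a), 0.2, "a"),
                             channel_image(f(a + 5), 0.2, "b"), f(40), f(60))
  expect_identical(r1, r2)
  expect_warning(v <- colocalization_ratio(cha, cha, 1e9, 50), "undefined")
  expect_true(is.na(v))
})

test_that("colocalization ratio equals the planted overlap fraction", {
  sp <- scene_spec(n_cells = 3, markers = list(
    marker_spec("Iba1", nucleus_level = 150, cytosol_level = 150),
    marker_spec("XPO1", overlap_with = list(channel = "Iba1", fraction = 0.35,
                                            level = 300))), seed = 80)
  sc <- generate_scene(sp)
  r <- colocalization_ratio(sc$channels$Iba1, sc$channels$XPO1,
                            sc$spec$background_level + 75,
                            sc$spec$background_level + 150)
  expect_equal(r, sc$ground_truth$overlap$fraction_realized, tolerance = 1e-12)
  expect_equal(r, 0.35, tolerance = 0.02)
})

test_that("line profiles interpolate exactly and preserve colocalized structure", {
  flat <- channel_image(matrix(42, 30, 30), 0.5, "f")
  lp <- line_profile(flat, c(5, 5), c(25, 25), n_samples = 50)
  expect_equal(lp$f, rep(42, 50))
  expect_equal(max(lp$distance_um), sqrt(2 * 20^2) * 0.5)
  grad <- channel_image(matrix(rep(0:29, each = 30), 30), 0.5, "g")
  lp2 <- line_profile(grad, c(15, 1), c(15, 30), n_samples = 30)
  expect_equal(lp2$g, 0:29)
  # two identical channels: correlation 1 along any line
  sp <- scene_spec(n_cells = 2, markers = list(
    marker_spec("A", nucleus_level = 80, cytosol_level = 160)), seed = 81)
  sc <- generate_scene(sp)
  two <- list(A = sc$channels$A, B = sc$channels$A)
  lp3 <- line_profile(two, c(10, 10), c(500, 500), n_samples = 200)
  expect_equal(stats::cor(lp3$A, lp3$B), 1.0)
  expect_error(line_profile(flat, c(5, 5), c(5, 5)), "differ")
  expect_error(line_profile(flat, c(0, 5), c(25, 25)), "inside")
})

test_that("normalization to control means per experiment", {
  tab <- data.frame(group = c("ctrl", "ctrl", "mut", "ctrl", "mut"),
                    experiment = c("e1", "e1", "e1", "e2", "e2"),
                    value = c(8, 12, 20, 20, 20))
  out <- normalize_to_control(tab, "ctrl")
  expect_equal(out$value, c(0.8, 1.2, 2.0, 1.0, 1.0))
  for (e in c("e1", "e2"))
    expect_equal(mean(out$value[out$group == "ctrl" & out$experiment == e]), 1.0)
  same <- data.frame(group = "ctrl", experiment = "e1", value = rep(3, 4))
  expect_true(all(normalize_to_control(same, "ctrl")$value == 1))
  bad <- data.frame(group = "mut", experiment = "e3", value = 1)
  expect_error(normalize_to_control(bad, "ctrl"), "e3")
})
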