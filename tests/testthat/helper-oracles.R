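# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: masked means enumerate pixels in an explicit loop,
# dilation enumerates pairwise distances, and the Mann-Whitney oracle
# counts (x > y) pairs per split.

# mean over mask by explicit pixel enumeration (same multiset, same mean())
bf_masked_mean <- function(pixels, mask) {
  vals <- numeric(0)
  for (ci in seq_len(ncol(pixels)))
    for (ri in seq_len(nrow(pixels)))
      if (mask[ri, ci]) vals <- c(vals, pixels[ri, ci])
  mean(vals)
}

# Euclidean dilation by pairwise distance enumeration
bf_dilate <- function(mask, r_px) {
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (ci in seq_len(ncol(mask)))
    for (ri in seq_len(nrow(mask)))
      out[ri, ci] <- min((src[, 1] - ri)^2 + (src[, 2] - ci)^2) <= r_px^2
  out
}

# random connected blob: union of a few overlapping disks
random_blob <- function(shape = c(40, 40), seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, shape[1], shape[2])
  ctr <- c(runif(1, 12, shape[1] - 12), runif(1, 12, shape[2] - 12))
  for (k in 1:3) {
    c2 <- ctr + runif(2, -3, 3)
    r <- runif(1, 3, 7)
    m <- m | rasterize_ellipse(shape, c2, r, r)
  }
  m
}

# exact two-sided Mann-Whitney p by pair counting over all group splits
bf_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  cmp <- outer(pooled, pooled, function(a, b) (a > b) + 0.5 * (a == b))
  diag(cmp) <- 0
  u_of <- function(sel) {
    other <- setdiff(seq_len(n), sel)
    sum(cmp[sel, other])
  }
  U <- u_of(seq_len(n1))
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, u_of)
  list(statistic = U,
       p.value = min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9))))
}

# scene helpers reused across test files
cn_scene <- function(cn, seed, noise = FALSE, n_cells = 8) {
  lv <- if (cn >= 1) c(100, 100 * cn) else c(200, 200 * cn)
  generate_scene(scene_spec(
    n_cells = n_cells,
    markers = list(marker_spec("M", nucleus_level = lv[1], cytosol_level = lv[2])),
    noise = if (noise) list(gaussian_sd = min(lv) / 10, poisson = TRUE)
            else list(gaussian_sd = 0, poisson = FALSE),
    seed = seed))
}

recover_cn <- function(scene) {
  nuclei <- segment_nuclei(scene$channels$DNA)
  cells <- suppressWarnings(segment_cell(scene$channels$M, nuclei))
  bg <- estimate_background(scene$channels$M, lapply(cells, `[[`, "cell_mask"))
  vapply(cells, function(cl)
    suppressWarnings(cn_ratio(scene$channels$M, cl, as.numeric(bg))), 0)
}

gt_cells <- function(scene) {
  lapply(seq_along(scene$ground_truth$masks), function(i) {
    m <- scene$ground_truth$masks[[i]]
    segmented_cell(i, m$nucleus, m$cell)
  })
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
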