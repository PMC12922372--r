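#!/usr/bin/env Rscript

# Simulate the study's imaging cohort: two genotype groups (control and
# mutant) of 3 animals each, 2 fields per animal, with per-cell ground
# truth. The mutant group carries the two hallmark perturbations measured
# downstream: cytoplasmic mislocalization of the export receptor (higher
# XPO1 C/N ratio) and a discontinuous nucleoporin rim (higher gap
# fraction). Writes TIFFs, sidecar metadata, ground truth and the sample
# sheet under results/data/.

library(nctquant)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed0 <- 20260921L
set.seed(seed0)

groups <- c(ctrl = 150, mut = 260)      # planted XPO1 cytosol level (nucleus 100)
gapfrac <- c(ctrl = 0.05, mut = 0.35)   # planted FG-Nup rim gap fraction
rows <- list()
for (g in names(groups)) {
  for (animal in 1:3) {
    # animal-level (cluster) variation on top of the group effect
    cyt_mult <- exp(rnorm(1, 0, 0.08))
    gap_jit <- max(0, gapfrac[[g]] + rnorm(1, 0, 0.03))
    for (field in 1:2) {
      sp <- scene_spec(
        n_cells = 4,
        markers = list(
          marker_spec("XPO1", nucleus_level = 100,
                      cytosol_level = groups[[g]] * cyt_mult),
          marker_spec("FGNup", ring_level = 300, gap_fraction = gap_jit)),
        noise = list(gaussian_sd = 10, poisson = TRUE),
        seed = seed0 + 1000 * (g == "mut") + 100 * animal + field)
      f <- file.path(out_dir, sprintf("%s_a%d_f%d.tif", g, animal, field))
      write_scene(generate_scene(sp), f)
      rows[[length(rows) + 1L]] <- data.frame(
        image = f, group = g, cluster = sprintf("%s_a%d", g, animal),
        experiment = "exp1", dna_channel = "DNA", marker_channel = "XPO1")
    }
  }
}
ss <- do.call(rbind, rows)
write.csv(ss, file.path(out_dir, "sample_sheet.csv"), row.names = FALSE)
cat(sprintf("simulated %d images (%d animals per group, 4 cells each)\n",
            nrow(ss), 3))
cat(sprintf("planted XPO1 C/N: ctrl %.2f, mut %.2f; FG-Nup gap fraction: ctrl %.2f, mut %.2f\n",
            groups[["ctrl"]] / 100, groups[["mut"]] / 100,
            gapfrac[["ctrl"]], gapfrac[["mut"]]))
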