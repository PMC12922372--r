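#!/usr/bin/env Rscript

# Human-readable summary: per-metric group distributions in the box-plot
# convention (median, quartiles, 10-90 range) plus significance stars.

library(nctquant)

tab <- read.csv("results/measurements.csv")
tests <- list()
for (m in unique(tab$metric))
  tests[[m]] <- cluster_robust_rank_ttest(tab[tab$metric == m, ],
                                          "value", "group", "cluster")
rep_lines <- write_report(list(measurements = tab, tests = tests))
writeLines(rep_lines)
writeLines(rep_lines, "results/report.txt")
cat("wrote results/report.txt\n")
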