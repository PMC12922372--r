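---
title: "Quantifying nucleocytoplasmic transport disruption: models, metrics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleocytoplasmic transport disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nctquant)
```

## The measurement problem

Disruption of nucleocytoplasmic transport (NCT) is a recurring pathological
signature in ALS and related neurodegenerative disease. In fluorescence
micrographs it manifests as a handful of quantifiable geometric and
intensity phenotypes: export and import factors (XPO1, RanGAP1) shifting
from the nucleus into the cytosol; loss of nucleoporin signal at the
nuclear rim; fragmentation of the FG-Nup rim into discontinuous stretches;
cytoplasmic puncta of transport factors; and overlap of transport-factor
signal with microglial markers. `nctquant` implements each of these
readouts as a deterministic function of a segmented cell and an intensity
image, plus the clustered rank-based inference needed to compare them
across groups of animals or cell lines.

Because cell-level measurements from the same animal (or staining batch)
are correlated, treating cells as independent replicates inflates the
false-positive rate dramatically — the package's own null simulations put
the naive rank ANOVA near 80% rejection at nominal 5% under an
intra-cluster correlation of 0.3. The inference stack therefore treats the
cluster, not the cell, as the unit that carries degrees of freedom.

## Compartment model

Every metric consumes a `segmented_cell`: boolean masks for nucleus, whole
cell, cytosol and optional envelope rings, with the algebra enforced at
construction:

* `cytosol = cell AND NOT nucleus` (the "whole cell and not nucleus" mask
  logic familiar from imaging flow cytometry);
* nuclear boundaries come from the DNA counterstain (global threshold,
  default Otsu; fixed-value and percentile thresholds are available because
  vendor auto-thresholds differ), hole-filled, minimum-area filtered
  (default 10 µm²);
* cytosolic boundaries come from a cytosolic marker channel; foreground
  blobs containing several nuclei are split by a geodesic nearest-nucleus
  partition, and each cell mask contains its nucleus by construction;
* the laminar ring is `dilate(nucleus, outer) AND NOT dilate(nucleus,
  inner)` with exact Euclidean disk dilation; the default is inner 0 µm,
  outer 1.3 µm. Micrometre offsets convert to pixels by round-half-up, and
  offsets that round to zero pixels raise an error rather than silently
  measuring nothing.

Background is the median intensity outside all cell masks dilated by a
2-pixel guard band; the guard width and statistic are configurable because
background regions are never specified precisely in imaging protocols.

## The metrics

* **C/N ratio** — `(mean cytosol − background) / (mean nucleus −
  background)`. The reciprocal (`nc_gradient`) serves nuclear-high markers
  such as Ran. Non-positive denominators yield `NA` with a logged warning;
  undefined ratios are excluded, never clipped or imputed.
* **Laminar intensity** — background-subtracted mean over the 1.3 µm ring.
* **Envelope / nucleoplasm ratio** — mean of a thin (1 px) band outside
  the nuclear boundary divided by the nucleoplasm mean (nucleus eroded by
  2 px). Here the nucleoplasm is the normalizer, so no separate background
  is subtracted; this mirrors rim quantification in postmortem tissue where
  no cytosolic counterstain is available. The acquisition literature this
  emulates states band widths inconsistently (a "1-pixel ≈ 0.3 µm" band
  and a "1.5-pixel ≈ 4.5 µm" perinuclear region cannot share a
  magnification), so both widths are exposed as configuration
  (`envelope_band_px`, `perinuclear_band_um`) and neither is hard-coded.
* **Puncta** — connected components above an intensity threshold,
  filtered by area bounds, optional roundness (`4πA/P²`, default minimum
  0.6) and optional centroid distance to the nuclear envelope (default
  maximum 2 µm). The roundness and proximity defaults operationalize the
  rule that tissue FG-Nup puncta are "round accumulations close to the
  envelope"; both are configuration, not truth.
* **Continuity index** — the envelope profile samples, at every traced
  boundary pixel, the maximum ring intensity along the outward normal
  within the ring width; the index is the supra-threshold arc length over
  the perimeter (1 = unbroken rim). Fragment and gap counts are maximal
  runs merged circularly across the trace start. The binarization
  threshold is a free parameter: the default heuristic is `background +
  0.5 × (median ring intensity − background)`, but planted or calibrated
  levels should be passed explicitly — the heuristic degrades when half
  the rim is missing, since the median itself then sits between signal and
  background.
* **Colocalization ratio** — `|A∧B| / |A|` on thresholded masks, per
  image. This is deliberately the area-overlap statistic, not Pearson or
  Manders correlation; it is invariant under any strictly monotone
  intensity rescaling applied jointly with its threshold.
* **Circularity** — `4πA/P²` with the same perimeter estimator as the
  continuity index.

### Perimeter estimation

Perimeters (circularity, envelope arc length, puncta roundness) use a
Moore boundary trace with Vossepoel–Smeulders corrected weights: 0.980 per
axial step, 1.406 per diagonal step, −0.091 per direction change. A naive
1/√2-weighted chain walk overestimates a digitized circle's perimeter by
about 5% (and the Moore trace, which visits corner pixels a chain code
would cut, by more), which would bias the circularity of a 50-pixel disk
to ≈0.90. With the corrected weights the same disk measures 1.012, and a
rasterized disk perimeter is within 1% of 2πr. The continuity index, being
a ratio of arc lengths, is nearly estimator-invariant; circularity is not,
which is why the corrected estimator is the package-wide rule. ImageJ's
exact estimator is not replicated; small rasterized disks can still score
roundness slightly above 1, which the default puncta roundness floor of
0.6 tolerates by design.

## Rank-based cluster-robust inference

For k groups the omnibus test is a one-way ANOVA on mid-ranks: ranks are
computed once jointly over all cells, regressed on group indicators by
least squares, and the coefficient covariance is the cluster-robust
sandwich with a CR2-type small-sample adjustment — residuals of cluster g
are premultiplied by `(I − H_gg)^{−1/2}` before entering the meat. With
the few clusters typical of animal studies (3–5 per group), the
unadjusted CR0 sandwich is anti-conservative; CR0 remains available by
configuration for comparison. Per-contrast degrees of freedom follow the
Bell–McCaffrey Satterthwaite construction; the omnibus Wald F uses the
smallest pairwise Satterthwaite df as its denominator reference, a
conservative small-sample choice driven by the cluster count. Pairwise
contrasts are adjusted by the studentized-range (Tukey) distribution at
their robust df. Tukey on robust contrasts is an approximation — the
classical derivation assumes homoskedastic equal-n means — so Holm is
offered as an alternative; the family must always be the complete set of
k(k−1)/2 pairs.

Two-group comparisons use the same machinery with k = 2 and no
multiplicity adjustment; ranks are recomputed over the two groups being
compared (joint ranking is used only within the ANOVA family). A plain
two-sided Mann–Whitney U is included for unclustered comparisons: exact
enumeration of the permutation distribution of U (on mid-ranks, so ties
are exact) when the pooled sample has at most 20 observations, and the
tie-corrected continuity-corrected normal approximation above that.

Under the package's null simulation (3 groups × 5 clusters × 40 cells,
intra-cluster correlation 0.3, 1000 replicates) the cluster-robust
omnibus rejects at 5.7–7.5% across seed blocks at nominal 5%, the Tukey
family-wise error stays below 8%, and the naive rank ANOVA on the same
draws rejects near 80% — the quantitative case for the adjustment.

## What the synthetic generator emulates — and what it does not

`generate_scene()` builds fields of non-overlapping cells: elliptical
nuclei (axis ratio ≤ 1.3 by default — nuclear shape is treated as largely
preserved, which also keeps circularity ground truth analytic) inside
concentric elliptical somata, a DNA channel, and per-marker nucleus /
cytosol / ring / puncta / overlap structure with every planted parameter
recorded as ground truth. Defaults are chosen for a high-magnification
confocal field of spinal motor neurons: 0.2 µm/px, nuclei ~5 µm radius,
somata ~9 µm, 12-bit-scale intensities, and a cytosolic annulus of at
least 2.5 µm so every compartment is measurable. Rim gaps are 1–3
contiguous arcs (uniformly placed, disjoint with margins) whose total
arc length — computed by elliptic arc-length parametrization, not by
angle — equals the planted gap fraction. Overlap channels copy an exact
pixel fraction of the reference channel's foreground, so the planted
colocalization ratio is exact by construction. Noise is Poisson on
(signal + background) followed by additive Gaussian read noise, the
standard fluorescence camera model; bit depth and SNR are choices, not
facts, and tests sweep them.

Clustered cohorts (`generate_cohort()`) are additive: baseline + group
effect + cluster intercept `N(0, σ_c²)` + residual `N(0, σ_e²)`, optionally
exponentiated (lognormal), with the implied intra-cluster correlation
`σ_c²/(σ_c²+σ_e²)`. Defaults match the calibration design above.

The generator deliberately omits: point-spread-function blur, 3-D stacks,
tissue autofluorescence, cell-type morphology (microglial ramification),
chromatin texture, and segmentation-adversarial cell packing. Passing
recovery tests on these scenes therefore demonstrates that the measurement
operators are correct and unbiased on their own terms — not that
segmentation is robust to the pathology of real tissue. On real images the
thresholds in `default_config()` are the knobs that matter, and all of
them are recorded in the effective-config dump of every pipeline run.

## Numerical choices

* µm→px conversions round half up (`floor(x + 0.5)`); all masks are
  boolean matrices indexed `[row, col]`, pixel centres at integer
  coordinates.
* Dilation/erosion are exact Euclidean (distance-transform thresholding),
  not approximate structuring-element brushes, so ring areas satisfy
  `|ring| = |dilate_outer| − |dilate_inner|` exactly.
* Boundary tracing starts at the topmost-then-leftmost boundary pixel with
  a fixed orientation, making every profile deterministic.
* CR2 inverse square roots clip eigenvalues at 1e−12; an all-tied response
  yields F = 0, p = 1 rather than 0/0.
* Degenerate inputs error early and specifically: constant images (no
  threshold), multiply-connected nuclei, empty rings, offsets below one
  pixel, experiments without control cells, groups with fewer than two
  clusters.
* Scene TIFFs store integers as 16-bit with a YAML sidecar for pixel size
  and channel names; reading resolves pixel size from sidecar, then an
  explicit override (override wins with a warning), and otherwise errors —
  never a silent default.

## Problem sizes used in validation

The test-suite and acceptance script sizes are: 50 randomized masks for
bit-identical oracle agreement; 200 cells per planted C/N ∈ {0.5, 2, 4} at
SNR 10 (median relative error ≈ 0.3%, tolerance 10%) and 40 noise-free
(error 0 at tolerance 2%); 36 cells per noise setting for gap fractions
{0, 0.25, 0.5} (max error ≈ 0.05 noise-free band, 0.10 at SNR 10, gap
counts exact); 100 two-cell images for puncta sensitivity/false-detection
at SNR 10 (observed 100% / 0%); 1000 null replicates for calibration; and
all Mann–Whitney group sizes up to 8 against exact enumeration.

## Known limitations

Single 2-D planes only; no machine-learned or interactive segmentation;
colocalization is the area-ratio statistic only; Tukey-on-robust-SEs and
the omnibus df rule are small-sample approximations rather than exact
distributional results; and the continuity threshold ultimately encodes a
judgment about what counts as "signal" at the rim — report it alongside
any continuity index.
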