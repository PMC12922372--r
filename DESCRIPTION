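Package: nctquant
Title: Quantification of Nucleocytoplasmic Transport Disruption from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-cell image-quantification metrics for nucleocytoplasmic
    transport readouts in multi-channel fluorescence microscopy
    (cytosol-to-nucleus intensity ratios, nuclear-envelope laminar
    intensity, envelope continuity index, puncta calling with size and
    shape constraints, thresholded-mask colocalization ratios), a
    rank-based one-way ANOVA and two-sample testing stack with
    cluster-robust (CR2-type) standard errors, Satterthwaite degrees of
    freedom and Tukey adjustment for clustered cell-level data, and a
    synthetic microscopy-scene and clustered-cohort generator that
    provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
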