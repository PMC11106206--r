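Package: ichwmi
Title: Gene Screening and Diffusion-Tensor White-Matter Injury Analysis for
    Intracerebral Hemorrhage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the two computational arms of an intracerebral
    hemorrhage (ICH) white-matter injury study. The gene-screening arm
    combines a leave-one-out SVM-validated within-group-variance prefilter,
    weighted gene co-expression network module detection (soft threshold,
    topological overlap, module eigengenes, module membership and gene
    significance), per-gene differential-expression testing with
    Benjamini-Hochberg correction, and the set-intersection funnel that
    yields candidate and target genes. The imaging arm fits diffusion
    tensors to multi-shell diffusion-weighted MRI, computes fractional
    anisotropy (FA) maps, summarises FA over paired regions of interest in
    the corpus callosum and internal capsule, and performs percentile
    bootstrap interval estimation and Fisher-Pitman permutation inference
    with omnibus-then-pairwise gatekeeping. A synthetic-data module
    generates block-correlated expression matrices, diffusion phantoms with
    Rician noise, and behavioural trial outcomes with known ground truth so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
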