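# ichwmi

Gene screening and diffusion-tensor statistics for intracerebral
hemorrhage (ICH) white-matter injury studies.

After an intracerebral hemorrhage, the surrounding white matter degrades;
two complementary kinds of evidence localise the molecular players and
quantify the damage. `ichwmi` implements both computational arms as a
single tested R package:

* **Gene screening.** A funnel that narrows a genes-by-samples expression
  matrix down to a handful of target genes: (1) removal of the 30% of
  genes with minimal pooled within-group variance, validated by
  leave-one-out linear-SVM accuracy and pooled F1; (2) weighted
  co-expression network analysis — soft threshold `a_ij = |cor|^beta`
  chosen by scale-free fit R², topological overlap matrix, average-linkage
  module detection with eigengene merging (`minModuleSize = 80`,
  `mergeCutHeight = 0.20`), module–trait correlation, and selection of
  interesting genes by module membership MM > 0.9 and gene significance
  GS (−log10 p) > 0.85; (3) per-gene pooled-variance t tests with
  Benjamini–Hochberg FDR and the |fold change| > 2, q < 0.05 thresholds;
  (4) exact set intersections producing candidate and finalist genes.
* **DTI white-matter statistics.** Log-linear least-squares diffusion
  tensor fitting from multi-shell DWI (b = 1000/2000 s/mm², 30
  directions, 5 b0), fractional anisotropy
  `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2) / sum(lambda_i^2))`,
  mean FA over 3×3×3 ROIs (9 in-plane voxels × 3 slices) in corpus
  callosum and internal capsule, right/left FA ratios over paired ROIs,
  10,000-resample percentile bootstrap CIs, and Fisher–Pitman permutation
  tests (exact enumeration or Monte Carlo) with omnibus-then-pairwise
  gatekeeping over the 3-group × 6-measure (18-cell) design.
* **Synthetic data with ground truth.** Block-correlated expression
  matrices (latent-factor modules, group shifts, noise genes), 3-D tensor
  phantoms with Rician noise, and behavioural trial draws — so every stage
  is testable offline.

## Worked example

Screen a synthetic dataset with one trait-associated module, then quantify
a phantom tract:

```r
library(ichwmi)

d <- gen_expression(synth_expression_spec(
  n_genes = 500, n_samples_per_group = 6,
  groups = c("perihematomal", "contralateral"),
  module_sizes = c(150, 150, 150), within_module_cor = 0.8,
  group_shift = c(2.5, 0, 0), seed = 19))

cfg <- pipeline_config(filter_fraction = 0.1, beta_candidates = c(2, 4, 6),
                       mm_thr = 0.8, gs_thr = 1.3, fc_thr = 1.2)
rep <- run_gene_screen(d$expr, trait = d$truth$trait, cfg = cfg)
rep$funnel
#> <screen_funnel>
#>   interesting  150
#>   degs_tissue  162
#>   degs_blood   162
#>   candidates   162
#>   finalists    146
#>   finalists: G00001, G00002, G00003, G00004, G00005, G00006, G00007, G00008, ... (146 total)
```

146 of the 150 genes of the planted trait-associated module survive the
whole funnel (interesting ∩ both DEG lists); no background gene does. The
published-list worked example reproduces the 8 → 3 reduction exactly:

```r
candidates <- gene_set(c("OLIG2", "MGLL", "CMTM5", "COL9A2", "PCOLCE2",
                         "SDC2", "SLC45A3", "RHOBTB1"))
interesting <- gene_set(c("CMTM5", "COL9A2", "SLC45A3", "MBP", "PLP1"))
intersect_sets(list(candidates, interesting))$members
#> [1] "CMTM5"   "COL9A2"  "SLC45A3"
```

Imaging arm on a noisy phantom (tract eigenvalues
(1.7, 0.3, 0.2)×10⁻³ mm²/s, true FA 0.836, SNR 30):

```r
ph <- gen_dwi_phantom(phantom_spec(shape = c(10, 10, 6), regions = list(
  list(name = "tract", voxels = voxel_block(2, 4, 2, 4, 1, 3),
       evals = c(1.7e-3, 0.3e-3, 0.2e-3), dir = c(0, 1, 0))),
  snr = 30, seed = 2), gen_scheme(30, c(1000, 2000), 5))
fa <- compute_fa_map(ph$dwi)
rois <- roi_set(data.frame(name = "CC_R_01", structure = "CC", side = "right",
                           center_x = 3, center_y = 3, center_z = 2, pair = NA))
roi_mean_fa(fa, rois)
#>      name structure  side   mean_fa n_inplane m_slices n_missing pair
#> 1 CC_R_01        CC right 0.8341111         9        3         0   NA

b <- bootstrap_ci(c(0.52, 0.48, 0.55, 0.49, 0.51), seed = 1)
sprintf("mean %.3f, 95%% CI [%.3f, %.3f]", b$point_estimate, b$ci_low, b$ci_high)
#> [1] "mean 0.510, 95% CI [0.490, 0.532]"

fisher_pitman_2sample(c(0.52, 0.48, 0.55), c(0.31, 0.29, 0.35))$p
#> [1] 0.1   # exact: 2 of the 20 possible relabelings reach the observed gap
```

The ROI mean FA (0.834) sits within 0.002 of the prescribed tract FA; with
n = 3 per group, 0.1 is the smallest two-sided p the exact Fisher–Pitman
test can produce, which is why the study scales inference across many ROIs
per structure.

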