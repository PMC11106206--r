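# Shared fixtures, built in code at test time.

# Benchmark expression set: 3 planted modules (cor 0.8, size 150) on a
# 2-group, 12-sample design, plus background noise genes.
benchmark_expression <- function(seed = 7, n_genes = 500, shift = c(2, 0, 0)) {
  gen_expression(synth_expression_spec(
    n_genes = n_genes, n_samples_per_group = 6, groups = c("peri", "contra"),
    module_sizes = c(150, 150, 150), within_module_cor = 0.8,
    group_shift = shift, noise_sd = 1, seed = seed))
}

# Cleanly separable two-group set: independent DE genes shifted by 3 SD
# (no shared factor, so the group means cannot overlap by a correlated
# factor draw).
separable_expression <- function(seed = 8) {
  gen_expression(synth_expression_spec(
    n_genes = 500, n_samples_per_group = 6, groups = c("peri", "contra"),
    module_sizes = integer(0), de_fraction = 0.3, group_shift = 3,
    noise_sd = 1, seed = seed))
}

# Small two-region phantom: one anisotropic tract block on isotropic
# background.
tract_phantom <- function(snr = Inf, seed = 1,
                          evals = c(1.7e-3, 0.3e-3, 0.2e-3)) {
  spec <- phantom_spec(
    shape = c(10, 10, 6),
    regions = list(list(name = "tract",
                        voxels = voxel_block(2, 4, 2, 4, 1, 3),
                        evals = evals, dir = c(0, 1, 0))),
    s0 = 1000, snr = snr, seed = seed)
  gen_dwi_phantom(spec, gen_scheme(30, c(1000, 2000), 5))
}

# Symmetric left/right two-tract phantom with optional right-side FA
# suppression (right eigenvalues pulled toward their mean by `suppress`).
paired_phantom <- function(suppress = 0, snr = Inf, seed = 1) {
  ev <- c(1.7e-3, 0.3e-3, 0.2e-3)
  evr <- ev + suppress * (mean(ev) - ev)
  spec <- phantom_spec(
    shape = c(16, 10, 6),
    regions = list(
      list(name = "left_tract", voxels = voxel_block(2, 4, 3, 5, 1, 3),
           evals = ev, dir = c(0, 1, 0)),
      list(name = "right_tract", voxels = voxel_block(11, 13, 3, 5, 1, 3),
           evals = sort(evr, decreasing = TRUE), dir = c(0, 1, 0))),
    s0 = 1000, snr = snr, seed = seed)
  gen_dwi_phantom(spec, gen_scheme(30, c(1000, 2000), 5))
}

paired_rois <- function() {
  roi_set(data.frame(
    name = c("CC_R_01", "CC_L_01"), structure = "CC",
    side = c("right", "left"),
    center_x = c(12, 3), center_y = 4, center_z = 2,
    pair = c("CC_L_01", NA)))
}

# Integer-positional gene subset of an expr_matrix.
subset_genes_for_test <- function(x, idx) {
  expression_matrix(x$values[idx, , drop = FALSE], x$gene_ids[idx],
                    x$sample_ids, x$sample_groups)
}

# Independent BH step-up oracle: sort, compare p_(i) * m / i, cummin from
# the top, map back.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force TOM by triple loop.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  t_out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    t_out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t_out
}
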