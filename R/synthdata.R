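#' Specify a synthetic expression dataset
#'
#' Describes a block-correlated genes-by-samples dataset with known ground
#' truth: `n_modules` gene modules each driven by a shared latent factor
#' (so the expected pairwise correlation inside module k equals
#' `within_module_cor[k]`), optional group-specific mean shifts that create
#' true differentially expressed genes, and i.i.d. Gaussian noise genes
#' filling the remainder. Values are on a log-like scale; noise is Gaussian.
#'
#' @param n_genes Total gene count.
#' @param n_samples_per_group Samples per group (scalar or one per group).
#' @param groups Character vector of group labels (>= 1).
#' @param module_sizes Integer vector of module sizes; the sum must not
#'   exceed `n_genes`.
#' @param within_module_cor Expected pairwise correlation within each module,
#'   in `[0, 1)`; scalar or one per module.
#' @param group_shift Mean shift, in units of `noise_sd`, applied to each
#'   module's genes in the shifted group (`shift_group`); scalar or one per
#'   module. Modules with nonzero shift contribute true DE genes.
#' @param shift_group Label of the group receiving the shift (default: the
#'   first group).
#' @param noise_sd Residual standard deviation (> 0).
#' @param de_fraction Fraction of the non-module ("noise") genes that also
#'   receive the shift `max(group_shift)`, as isolated true DE genes outside
#'   any module. Default 0.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A list of class `synth_expr_spec`.
#' @export
synth_expression_spec <- function(n_genes = 2000,
                                  n_samples_per_group = 7,
                                  groups = c("perihematomal", "contralateral"),
                                  module_sizes = c(150, 150, 150),
                                  within_module_cor = 0.8,
                                  group_shift = 0,
                                  shift_group = groups[1],
                                  noise_sd = 1,
                                  de_fraction = 0,
                                  seed = 1L) {
  groups <- as.character(groups)
  n_groups <- length(groups)
  n_samples_per_group <- rep_len(as.integer(n_samples_per_group), n_groups)
  n_modules <- length(module_sizes)
  within_module_cor <- rep_len(within_module_cor, n_modules)
  group_shift <- rep_len(group_shift, max(n_modules, 1L))
  assert_that(n_genes >= 1 && all(n_samples_per_group >= 1),
              "all counts must be >= 1")
  assert_that(sum(module_sizes) <= n_genes,
              "sum of module_sizes exceeds n_genes")
  assert_that(all(within_module_cor >= 0 & within_module_cor < 1),
              "within_module_cor must lie in [0, 1)")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  assert_that(de_fraction >= 0 && de_fraction <= 1,
              "de_fraction must lie in [0, 1]")
  assert_that(shift_group %in% groups, "shift_group must be one of groups")
  structure(
    list(n_genes = as.integer(n_genes),
         n_samples_per_group = n_samples_per_group, groups = groups,
         n_modules = n_modules, module_sizes = as.integer(module_sizes),
         within_module_cor = within_module_cor, group_shift = group_shift,
         shift_group = shift_group, noise_sd = noise_sd,
         de_fraction = de_fraction, seed = as.integer(seed)),
    class = "synth_expr_spec"
  )
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Genes in module k are `sqrt(rho_k) * f + sqrt(1 - rho_k) * eps`, scaled
#' by `noise_sd`, where `f` is a per-module latent factor shared across the
#' module and `eps` is i.i.d. standard normal, so the expected pairwise
#' within-module correlation is `rho_k`. True DE genes (module genes of
#' shifted modules, plus a `de_fraction` of noise genes) get
#' `group_shift * noise_sd` added in the `shift_group` samples.
#'
#' @param spec A [synth_expression_spec()].
#' @return A list with `expr` (an [expression_matrix()]) and `truth`, a
#'   truth bundle containing `module_labels` (integer per gene, 0 = none),
#'   `de_genes` (character vector), `factor_scores` (samples x modules) and
#'   `trait` (numeric indicator of the shifted group, one per sample).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_expr_spec"))
  n_samples <- sum(spec$n_samples_per_group)
  group_of <- rep(spec$groups, times = spec$n_samples_per_group)
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
  module_labels <- integer(spec$n_genes)
  if (spec$n_modules > 0) {
    module_labels[seq_len(sum(spec$module_sizes))] <-
      rep(seq_len(spec$n_modules), times = spec$module_sizes)
  }
  shifted_samples <- group_of == spec$shift_group

  with_local_seed(spec$seed, {
    vals <- matrix(rnorm(spec$n_genes * n_samples, sd = spec$noise_sd),
                   nrow = spec$n_genes, ncol = n_samples)
    factors <- matrix(rnorm(n_samples * max(spec$n_modules, 1L)),
                      nrow = n_samples)
    de_mask <- logical(spec$n_genes)
    for (k in seq_len(spec$n_modules)) {
      rows <- which(module_labels == k)
      rho <- spec$within_module_cor[k]
      vals[rows, ] <- spec$noise_sd *
        (sqrt(rho) * matrix(factors[, k], length(rows), n_samples,
                            byrow = TRUE) +
           sqrt(1 - rho) * matrix(rnorm(length(rows) * n_samples),
                                  nrow = length(rows)))
      if (spec$group_shift[k] != 0) {
        vals[rows, shifted_samples] <- vals[rows, shifted_samples] +
          spec$group_shift[k] * spec$noise_sd
        de_mask[rows] <- TRUE
      }
    }
    noise_rows <- which(module_labels == 0L)
    n_extra <- floor(spec$de_fraction * length(noise_rows))
    if (n_extra > 0) {
      extra <- noise_rows[seq_len(n_extra)]
      vals[extra, shifted_samples] <- vals[extra, shifted_samples] +
        max(spec$group_shift) * spec$noise_sd
      de_mask[extra] <- TRUE
    }
    sample_ids <- sprintf("S%02d_%s", seq_len(n_samples),
                          abbreviate(group_of, 4))
    expr <- expression_matrix(vals, gene_ids, sample_ids, group_of)
    truth <- list(module_labels = stats::setNames(module_labels, gene_ids),
                  de_genes = gene_ids[de_mask],
                  factor_scores = factors[, seq_len(max(spec$n_modules, 1L)),
                                          drop = FALSE],
                  trait = as.numeric(shifted_samples))
    list(expr = expr, truth = truth)
  })
}

#' Build a multi-shell diffusion acquisition scheme
#'
#' Returns the acquisition table used throughout the imaging arm: `n_b0`
#' rows at b = 0 followed by `n_dirs` unit gradient directions per nonzero
#' shell. Directions are laid out by the deterministic spherical-Fibonacci
#' construction, which is quasi-uniform on the sphere and reproducible.
#' The study protocol is b = 1000 and 2000 s/mm^2 in 30 directions plus
#' five b = 0 images, i.e. `gen_scheme(30, c(1000, 2000), 5)`.
#'
#' @param n_dirs Number of gradient directions per shell (>= 6; a symmetric
#'   tensor has 6 free components).
#' @param bvals Nonzero b-values, s/mm^2, one per shell.
#' @param n_b0 Number of b = 0 rows.
#' @return A `diffusion_scheme`: list with `b` (numeric per volume) and `g`
#'   (volumes x 3 unit direction matrix; zero rows for b = 0).
#' @export
gen_scheme <- function(n_dirs = 30, bvals = c(1000, 2000), n_b0 = 5) {
  assert_that(n_dirs >= 6,
              "at least 6 directions are needed to determine a tensor",
              class = "ichwmi_underdetermined_error")
  assert_that(all(bvals > 0), "bvals must be positive")
  dirs <- fibonacci_sphere(n_dirs)
  b <- c(rep(0, n_b0), rep(bvals, each = n_dirs))
  g <- rbind(matrix(0, n_b0, 3),
             do.call(rbind, replicate(length(bvals), dirs, simplify = FALSE)))
  structure(list(b = b, g = g), class = "diffusion_scheme")
}

# Spherical-Fibonacci point set: n quasi-uniform unit vectors.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Specify a diffusion phantom
#'
#' A 3-D voxel grid where named regions carry prescribed diffusion-tensor
#' eigenvalues and principal directions (think: high-FA corpus-callosum and
#' internal-capsule tract blocks on an isotropic background). Voxels not in
#' any region default to the `background` eigenvalues.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param regions List of regions, each a list with `name`, `voxels`
#'   (n x 3 matrix of 0-based voxel indices), `evals` (eigenvalues
#'   `lambda1 >= lambda2 >= lambda3`, mm^2/s) and `dir` (principal unit
#'   direction).
#' @param background Eigenvalues for voxels outside every region (isotropic
#'   by default).
#' @param s0 Baseline (b = 0) signal.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless. Rician noise with
#'   sigma = s0 / snr is applied to finite-SNR phantoms.
#' @param seed Integer seed for noise generation.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(12, 12, 9), regions = list(),
                         background = c(0.7e-3, 0.7e-3, 0.7e-3),
                         s0 = 1000, snr = Inf, seed = 1L) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape >= 1), "shape must be 3 positive dims")
  assert_that(s0 > 0, "s0 must be positive")
  assert_that(is.infinite(snr) || snr > 0, "snr must be positive or Inf")
  seen <- character(0)
  for (r in regions) {
    assert_that(all(c("name", "voxels", "evals", "dir") %in% names(r)),
                "each region needs name, voxels, evals, dir")
    v <- r$voxels
    assert_that(is.matrix(v) && ncol(v) == 3, "region voxels must be an n x 3 matrix")
    assert_that(all(v >= 0) && all(t(v) < shape),
                sprintf("region '%s' has voxels outside the grid", r$name))
    key <- apply(v, 1, paste, collapse = ",")
    assert_that(!any(key %in% seen), "region voxel sets must be disjoint")
    seen <- c(seen, key)
    ev <- r$evals
    assert_that(all(ev >= 0) && !is.unsorted(rev(ev)),
                "eigenvalues must be nonnegative and sorted descending")
    assert_that(abs(sqrt(sum(r$dir^2)) - 1) < 1e-8,
                "principal direction must be unit norm")
  }
  assert_that(all(background >= 0) && !is.unsorted(rev(background)),
              "background eigenvalues must be nonnegative, sorted descending")
  structure(list(shape = shape, regions = regions, background = background,
                 s0 = s0, snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Helper: axis-aligned voxel block
#'
#' Enumerates the 0-based voxel indices of the box `[x0, x1] x [y0, y1] x
#' [z0, z1]` (inclusive), for building phantom regions and ROIs.
#'
#' @param x0,x1,y0,y1,z0,z1 Inclusive 0-based bounds.
#' @return n x 3 integer matrix of voxel indices.
#' @export
voxel_block <- function(x0, x1, y0, y1, z0, z1) {
  as.matrix(expand.grid(x = x0:x1, y = y0:y1, z = z0:z1))
}

# Tensor from eigenvalues + principal direction: lambda1 along `dir`, the
# two minor eigenvectors completing an orthonormal frame.
tensor_from_axis <- function(evals, dir) {
  dir <- dir / sqrt(sum(dir^2))
  # any vector not parallel to dir
  aux <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- aux - sum(aux * dir) * dir
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(dir[2] * e2[3] - dir[3] * e2[2],
          dir[3] * e2[1] - dir[1] * e2[3],
          dir[1] * e2[2] - dir[2] * e2[1])
  V <- cbind(dir, e2, e3)
  V %*% diag(evals) %*% t(V)
}

#' Simulate a diffusion-weighted volume from a phantom
#'
#' Per voxel v and scheme row k the noiseless signal is
#' `S = s0 * exp(-b_k * g_k' D_v g_k)`. With finite SNR, Rician noise is
#' applied: the reported signal is the magnitude of the complex signal
#' perturbed by independent Gaussian noise of standard deviation
#' `sigma = s0 / snr` in each channel (the standard magnitude-MR model).
#'
#' @param spec A [phantom_spec()].
#' @param scheme A [gen_scheme()] acquisition.
#' @return A list with `dwi` (a `dwi_volume`: 4-D array plus scheme) and
#'   `truth` (per-voxel `fa` array, `evals` array `x,y,z,3`, and per-region
#'   voxel index lists).
#' @export
gen_dwi_phantom <- function(spec, scheme) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "diffusion_scheme"))
  dims <- spec$shape
  n_vol <- length(scheme$b)
  evals_arr <- array(rep(spec$background, each = prod(dims)),
                     dim = c(dims, 3))
  # voxel -> tensor map; default isotropic background
  tensor_of <- array(0, dim = c(dims, 6)) # Dxx Dyy Dzz Dxy Dxz Dyz
  bg <- tensor_from_axis(spec$background, c(1, 0, 0))
  tensor_of[, , , 1] <- bg[1, 1]; tensor_of[, , , 2] <- bg[2, 2]
  tensor_of[, , , 3] <- bg[3, 3]; tensor_of[, , , 4] <- bg[1, 2]
  tensor_of[, , , 5] <- bg[1, 3]; tensor_of[, , , 6] <- bg[2, 3]
  region_voxels <- list()
  for (r in spec$regions) {
    D <- tensor_from_axis(r$evals, r$dir)
    idx1 <- r$voxels + 1L # to 1-based
    for (i in seq_len(nrow(idx1))) {
      x <- idx1[i, 1]; y <- idx1[i, 2]; z <- idx1[i, 3]
      tensor_of[x, y, z, ] <- c(D[1, 1], D[2, 2], D[3, 3],
                                D[1, 2], D[1, 3], D[2, 3])
      evals_arr[x, y, z, ] <- r$evals
    }
    region_voxels[[r$name]] <- r$voxels
  }
  # signal: S[v, k] = s0 * exp(-b_k g' D g); vectorize over voxels
  nvox <- prod(dims)
  Tm <- matrix(tensor_of, nrow = nvox, ncol = 6)
  G <- scheme$g
  # quadratic form coefficients per scheme row
  Q <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
             2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  expo <- Tm %*% t(Q * scheme$b) # nvox x n_vol
  signal <- spec$s0 * exp(-expo)
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    signal <- with_local_seed(spec$seed, {
      re <- signal + matrix(rnorm(length(signal), sd = sigma), nrow = nvox)
      im <- matrix(rnorm(length(signal), sd = sigma), nrow = nvox)
      sqrt(re^2 + im^2)
    })
  }
  data4d <- array(signal, dim = c(dims, n_vol))
  fa_true <- array(apply(matrix(evals_arr, ncol = 3), 1,
                         function(ev) fa_from_eigenvalues(ev[1], ev[2], ev[3])),
                   dim = dims)
  list(dwi = dwi_volume(data4d, scheme),
       truth = list(fa = fa_true, evals = evals_arr,
                    region_voxels = region_voxels))
}

#' Simulate per-animal behavioural trial outcomes
#'
#' Draws, for each animal in each group, the number of successes out of
#' `n_trials` Bernoulli trials (the behavioural tests repeat each trial 10
#' times per animal).
#'
#' @param group_means Named numeric vector of per-group success
#'   probabilities in `[0, 1]`.
#' @param n_mice Animals per group.
#' @param n_trials Trials per animal (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `mouse`, `successes`, `trials`.
#' @export
gen_behavior_trials <- function(group_means, n_mice = 8, n_trials = 10,
                                seed = 1L) {
  assert_that(all(group_means >= 0 & group_means <= 1),
              "success probabilities must lie in [0, 1]")
  groups <- names(group_means) %||% paste0("group", seq_along(group_means))
  with_local_seed(seed, {
    do.call(rbind, lapply(seq_along(group_means), function(i) {
      data.frame(group = groups[i], mouse = seq_len(n_mice),
                 successes = rbinom(n_mice, n_trials, group_means[i]),
                 trials = n_trials)
    }))
  })
}
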