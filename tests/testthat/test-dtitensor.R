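test_that("FA formula: isotropy, maximal anisotropy, and reference value", {
  expect_equal(fa_from_eigenvalues(2e-3, 2e-3, 2e-3), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  # direct evaluation of the standard formula
  l <- c(1.7, 0.3, 0.2) * 1e-3
  lb <- mean(l)
  oracle <- sqrt(3 / 2) * sqrt(sum((l - lb)^2) / sum(l^2))
  expect_equal(fa_from_eigenvalues(l[1], l[2], l[3]), oracle)
  expect_equal(round(oracle, 3), 0.836)
  expect_equal(fa_from_eigenvalues(0, 0, 0), 0)
})

test_that("FA is permutation and scale invariant, and bounded in [0, 1]", {
  set.seed(53)
  for (i in 1:20) {
    l <- sort(runif(3, 0, 3e-3), decreasing = TRUE)
    fa <- fa_from_eigenvalues(l[1], l[2], l[3])
    expect_gte(fa, 0)
    expect_lte(fa, 1)
    expect_equal(fa, fa_from_eigenvalues(l[3], l[1], l[2]))
    expect_equal(fa, fa_from_eigenvalues(5 * l[1], 5 * l[2], 5 * l[3]))
  }
})

test_that("noiseless tensor fit recovers the generating eigenvalues", {
  ph <- tract_phantom(snr = Inf)
  tv <- fit_tensor(ph$dwi)
  # tract voxel
  ev <- tv$evals[3, 3, 2, ]
  truth <- c(1.7e-3, 0.3e-3, 0.2e-3)
  expect_lt(max(abs(ev - truth) / truth), 1e-8)
  # isotropic voxel d*I -> all eigenvalues d
  evb <- tv$evals[1, 1, 1, ]
  expect_lt(max(abs(evb - 0.7e-3) / 0.7e-3), 1e-8)
  expect_equal(exp(tv$ln_s0[1, 1, 1]), 1000, tolerance = 1e-8)
})

test_that("eigenvalues are invariant under rotation of the principal axis", {
  sch <- gen_scheme(30, c(1000, 2000), 5)
  evals <- c(1.7e-3, 0.3e-3, 0.2e-3)
  dirs <- list(c(0, 1, 0), c(1, 0, 0),
               c(1, 1, 1) / sqrt(3), c(0.6, 0, 0.8))
  fits <- lapply(dirs, function(dd) {
    spec <- phantom_spec(shape = c(3, 3, 3), regions = list(
      list(name = "t", voxels = matrix(c(1, 1, 1), 1), evals = evals,
           dir = dd)), snr = Inf)
    ph <- gen_dwi_phantom(spec, sch)
    fit_tensor(ph$dwi)$evals[2, 2, 2, ]
  })
  for (f in fits) expect_lt(max(abs(f - evals) / evals), 1e-8)
})

test_that("noiseless FA map reproduces the truth to 1e-8 relative", {
  ph <- tract_phantom(snr = Inf)
  fa <- compute_fa_map(ph$dwi)
  rel <- abs(fa - ph$truth$fa) / pmax(ph$truth$fa, 1e-3)
  expect_lt(max(rel), 1e-8)
})

test_that("noisy FA stays within Monte-Carlo tolerance of the truth", {
  ph <- tract_phantom(snr = 20, seed = 3)
  fa <- compute_fa_map(ph$dwi)
  tract <- ph$truth$region_voxels$tract + 1L
  vals <- fa[tract]
  truth <- fa_from_eigenvalues(1.7e-3, 0.3e-3, 0.2e-3)
  expect_lt(abs(mean(vals) - truth), 0.05)
})

test_that("unfittable voxels are flagged when too few usable rows remain", {
  ph <- tract_phantom(snr = Inf)
  d <- ph$dwi$data
  d[1, 1, 1, 1:60] <- 0 # only 5 usable rows left
  dwi <- dwi_volume(d, ph$dwi$scheme)
  tv <- fit_tensor(dwi)
  expect_false(tv$fittable[1, 1, 1])
  expect_true(is.na(compute_fa_map(dwi)[1, 1, 1]))
})

test_that("ROI means follow the flat-average oracle and report 9 x 3 geometry", {
  fa <- array(0, dim = c(10, 10, 6))
  vals <- array(seq_len(27) / 27, dim = c(3, 3, 3))
  fa[4:6, 4:6, 2:4] <- vals
  rois <- roi_set(data.frame(name = "CC_R_01", structure = "CC",
                             side = "right", center_x = 4, center_y = 4,
                             center_z = 2, pair = NA))
  st <- roi_mean_fa(fa, rois)
  expect_equal(st$n_inplane, 9)
  expect_equal(st$m_slices, 3)
  expect_equal(st$mean_fa, mean(vals), tolerance = 1e-12)
  # constant region -> the constant
  fa[4:6, 4:6, 2:4] <- 0.42
  expect_equal(roi_mean_fa(fa, rois)$mean_fa, 0.42)
  # ROI at the border errors with the ROI named
  bad <- roi_set(data.frame(name = "CC_R_02", structure = "CC",
                            side = "right", center_x = 0, center_y = 4,
                            center_z = 2, pair = NA))
  expect_error(roi_mean_fa(fa, bad), "CC_R_02",
               class = "ichwmi_roi_outside_error")
})

test_that("right/left ratios: symmetry gives 1, suppression shows up", {
  ph <- paired_phantom(suppress = 0)
  fa <- compute_fa_map(ph$dwi)
  st <- roi_mean_fa(fa, paired_rois())
  rat <- fa_ratios(st)
  expect_equal(rat$ratio, 1, tolerance = 1e-6)
  # ~40% eigenvalue shrinkage toward isotropy lowers the right-side ratio
  ph2 <- paired_phantom(suppress = 0.4)
  fa2 <- compute_fa_map(ph2$dwi)
  rat2 <- fa_ratios(roi_mean_fa(fa2, paired_rois()))
  truth_left <- fa_from_eigenvalues(1.7e-3, 0.3e-3, 0.2e-3)
  ev <- c(1.7e-3, 0.3e-3, 0.2e-3)
  evr <- ev + 0.4 * (mean(ev) - ev)
  truth_ratio <- fa_from_eigenvalues(evr[1], evr[2], evr[3]) / truth_left
  expect_equal(rat2$ratio, truth_ratio, tolerance = 1e-6)
  expect_lt(rat2$ratio, 0.8)
})

test_that("unpaired right ROIs are rejected", {
  st <- data.frame(name = c("CC_R_01", "CC_L_01"), structure = "CC",
                   side = c("right", "left"), mean_fa = c(0.5, 0.5),
                   n_inplane = 9, m_slices = 3, n_missing = 0,
                   pair = c(NA, NA))
  expect_error(fa_ratios(st), class = "ichwmi_unpaired_roi_error")
})

test_that("ROI mean FA degrades monotonically with isotropic replacement", {
  sch <- gen_scheme(30, c(1000, 2000), 5)
  block <- voxel_block(2, 4, 2, 4, 1, 3)
  means <- sapply(c(0, 9, 18, 27), function(n_iso) {
    keep <- if (n_iso == 0) block else block[-seq_len(n_iso), , drop = FALSE]
    regions <- if (nrow(keep) > 0)
      list(list(name = "t", voxels = keep,
                evals = c(1.7e-3, 0.3e-3, 0.2e-3), dir = c(0, 1, 0)))
    else list()
    ph <- gen_dwi_phantom(phantom_spec(shape = c(10, 10, 6),
                                       regions = regions, snr = Inf), sch)
    fa <- compute_fa_map(ph$dwi)
    rois <- roi_set(data.frame(name = "R1", structure = "CC", side = "right",
                               center_x = 3, center_y = 3, center_z = 2,
                               pair = NA))
    roi_mean_fa(fa, rois)$mean_fa
  })
  expect_true(all(diff(means) < 0))
})

test_that("NIfTI and FSL scheme round trips preserve the data", {
  tmp <- withr::local_tempdir()
  ph <- tract_phantom(snr = 20, seed = 4)
  nii <- file.path(tmp, "dwi.nii.gz")
  bval <- file.path(tmp, "bvals")
  bvec <- file.path(tmp, "bvecs")
  write_dwi(ph$dwi, nii, bval, bvec)
  back <- read_dwi(nii, bval, bvec)
  expect_equal(back$data, ph$dwi$data, tolerance = 1e-6)
  expect_equal(back$scheme$b, ph$dwi$scheme$b)
  expect_equal(back$scheme$g, ph$dwi$scheme$g, tolerance = 1e-12,
               ignore_attr = TRUE)
  fa <- compute_fa_map(ph$dwi)
  fa_path <- file.path(tmp, "fa.nii.gz")
  write_fa(fa, fa_path)
  expect_equal(as.numeric(read_fa(fa_path)), as.numeric(fa),
               tolerance = 1e-6)
  rois <- paired_rois()
  rp <- file.path(tmp, "rois.json")
  write_rois(rois, rp)
  back_rois <- read_rois(rp)
  expect_equal(back_rois$name, rois$name)
  expect_equal(back_rois$center_x, rois$center_x)
})
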