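#' Diffusion-weighted volume container
#'
#' @param data 4-D numeric array `(x, y, z, volume)`; the fourth dimension
#'   must match the scheme length and signals must be nonnegative.
#' @param scheme A [gen_scheme()] acquisition (or one read with
#'   [read_scheme()]).
#' @param mask Optional logical 3-D array restricting fitting.
#' @return A list of class `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  assert_that(length(dim(data)) == 4, "DWI data must be 4-D (x, y, z, volume)")
  assert_that(dim(data)[4] == length(scheme$b),
              "4th dimension must equal the number of scheme rows")
  assert_that(all(data >= 0), "signals must be nonnegative")
  if (!is.null(mask))
    assert_that(all(dim(mask) == dim(data)[1:3]), "mask dimensions mismatch")
  structure(list(data = data, scheme = scheme, mask = mask),
            class = "dwi_volume")
}

# Validate a scheme for tensor fitting: >= 6 distinct b>0 directions + a b0.
check_fittable <- function(scheme) {
  nz <- scheme$b > 0
  assert_that(sum(!nz) >= 1, "at least one b = 0 volume required")
  dirs <- unique(round(scheme$g[nz, , drop = FALSE], 10))
  assert_that(nrow(dirs) >= 6, "at least 6 distinct gradient directions required",
              class = "ichwmi_underdetermined_error")
  invisible(TRUE)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, ordinary least squares on
#' `ln S_k = ln S0 - b_k g_k' D g_k` with design row
#' `(-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1)`;
#' both shells are pooled into the single fit. Nonpositive signals are
#' excluded from that voxel's fit; voxels with fewer than 7 usable rows are
#' marked unfittable. The symmetric 3x3 tensor is eigen-decomposed per
#' voxel; eigenvalues are sorted descending and retained raw (negative
#' values are clamped to zero only when computing FA downstream).
#'
#' @param dwi A [dwi_volume()].
#' @return A list of class `tensor_volume`: `evals` (array x,y,z,3, sorted
#'   descending), `tensors` (array x,y,z,6: Dxx Dyy Dzz Dxy Dxz Dyz),
#'   `ln_s0` (array), `fittable` (logical array).
#' @export
fit_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  check_fittable(dwi$scheme)
  dims <- dim(dwi$data)[1:3]
  nvox <- prod(dims)
  n_vol <- dim(dwi$data)[4]
  G <- dwi$scheme$g
  b <- dwi$scheme$b
  X <- cbind(-b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3], 1)
  S <- matrix(dwi$data, nrow = nvox, ncol = n_vol)
  mask <- if (is.null(dwi$mask)) rep(TRUE, nvox) else as.vector(dwi$mask)
  usable <- S > 0
  coefs <- matrix(NA_real_, nvox, 7)
  fittable <- logical(nvox)
  full <- mask & rowSums(usable) == n_vol
  if (any(full)) {
    # shared design: one pseudo-inverse for all complete voxels
    pinv <- solve(crossprod(X), t(X))
    coefs[full, ] <- t(pinv %*% t(log(S[full, , drop = FALSE])))
    fittable[full] <- TRUE
  }
  partial <- which(mask & !full & rowSums(usable) >= 7)
  for (v in partial) {
    rows <- usable[v, ]
    fit <- stats::lm.fit(X[rows, , drop = FALSE], log(S[v, rows]))
    if (fit$rank == 7) {
      coefs[v, ] <- fit$coefficients
      fittable[v] <- TRUE
    }
  }
  evals <- matrix(NA_real_, nvox, 3)
  for (v in which(fittable)) {
    d <- coefs[v, ]
    D <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    evals[v, ] <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                       decreasing = TRUE)
  }
  structure(list(evals = array(evals, dim = c(dims, 3)),
                 tensors = array(coefs[, 1:6], dim = c(dims, 6)),
                 ln_s0 = array(coefs[, 7], dim = dims),
                 fittable = array(fittable, dim = dims)),
            class = "tensor_volume")
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(((l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2) /
#' (l1^2 + l2^2 + l3^2))` with `lbar = (l1 + l2 + l3) / 3`. FA is 0 for
#' isotropic diffusion and approaches 1 as diffusion collapses onto a
#' single axis. An all-zero triple returns 0 by convention. Vectorised over
#' its arguments.
#'
#' @param l1,l2,l3 Eigenvalues (any order; FA is permutation invariant).
#' @return FA in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- ifelse(den == 0, 0, sqrt(1.5) * sqrt(num / pmax(den, .Machine$double.xmin)))
  pmin(fa, 1)
}

#' Voxelwise FA map
#'
#' Composes [fit_tensor()] and [fa_from_eigenvalues()]; negative fitted
#' eigenvalues are clamped to zero for FA only. Unfittable voxels are `NA`.
#'
#' @param dwi A [dwi_volume()] (or a precomputed `tensor_volume`).
#' @return 3-D numeric array of FA values in `[0, 1]` (class `fa_volume`).
#' @export
compute_fa_map <- function(dwi) {
  tv <- if (inherits(dwi, "tensor_volume")) dwi else fit_tensor(dwi)
  dims <- dim(tv$evals)[1:3]
  ev <- matrix(tv$evals, ncol = 3)
  ev <- pmax(ev, 0)
  fa <- fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3])
  fa[!as.vector(tv$fittable)] <- NA_real_
  structure(array(fa, dim = dims), class = c("fa_volume", "array"))
}

#' ROI set constructor
#'
#' Each ROI is a fixed 3x3x3 voxel block identified by its 0-based center
#' voxel; "in-plane" is the first two (fastest) axes, slices run along the
#' third, so each ROI covers n = 9 in-plane voxels through m = 3 slices.
#' Right-side ROIs name their left partner via `pair` for the right/left
#' FA ratio (the pairing mirrors the study's manual position-matched ROIs:
#' 15 per side in the corpus callosum, 10 per side in the internal
#' capsule).
#'
#' @param rois Data frame (or list of lists) with columns `name`,
#'   `structure` (`"CC"` or `"IC"`), `side` (`"left"`/`"right"`),
#'   `center_x`, `center_y`, `center_z` (0-based), and `pair` (name of the
#'   opposite-side partner, `NA` for unpaired).
#' @param extent Cube edge length (default 3).
#' @return Data frame of class `roi_set`.
#' @export
roi_set <- function(rois, extent = 3) {
  if (!is.data.frame(rois)) {
    rois <- do.call(rbind, lapply(rois, function(r) {
      ctr <- as.numeric(unlist(r$center))
      data.frame(name = r$name, structure = r$structure, side = r$side,
                 center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
                 pair = if (is.null(r$pair)) NA_character_ else r$pair)
    }))
  }
  need <- c("name", "structure", "side", "center_x", "center_y", "center_z")
  assert_that(all(need %in% colnames(rois)), "missing ROI columns")
  if (!"pair" %in% colnames(rois)) rois$pair <- NA_character_
  assert_that(!anyDuplicated(rois$name), "ROI names must be unique")
  assert_that(all(rois$side %in% c("left", "right")),
              "side must be 'left' or 'right'")
  attr(rois, "extent") <- extent
  class(rois) <- c("roi_set", "data.frame")
  rois
}

#' Read / write ROI definitions as JSON
#'
#' The JSON dialect is an array of objects
#' `{"name": ..., "structure": "CC", "side": "right",
#'   "center": [x, y, z], "pair": ...}` with 0-based centers.
#'
#' @param path JSON file path.
#' @param rois A [roi_set()].
#' @return `read_rois` returns a [roi_set()].
#' @export
read_rois <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  roi_set(lst)
}

#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  lst <- lapply(seq_len(nrow(rois)), function(i) {
    out <- list(name = rois$name[i], structure = rois$structure[i],
                side = rois$side[i],
                center = c(rois$center_x[i], rois$center_y[i], rois$center_z[i]))
    if (!is.na(rois$pair[i])) out$pair <- rois$pair[i]
    out
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE)
  invisible(path)
}

#' Mean FA per ROI
#'
#' Arithmetic mean of the FA values over each ROI's `n x m` voxel block
#' (`n = 9` in-plane voxels through `m = 3` slices for the default 3x3x3
#' extent): `FAbar = (1/m)(1/n) sum_i sum_j FA_ij`. Missing (unfittable)
#' voxels are excluded and counted.
#'
#' @param fa A [compute_fa_map()] result (3-D array).
#' @param rois A [roi_set()].
#' @return Data frame of class `roi_stat`: `name`, `structure`, `side`,
#'   `mean_fa`, `n_inplane`, `m_slices`, `n_missing`, `pair`.
#' @export
roi_mean_fa <- function(fa, rois) {
  stopifnot(inherits(rois, "roi_set"))
  dims <- dim(fa)
  extent <- attr(rois, "extent")
  half <- (extent - 1) %/% 2
  out <- lapply(seq_len(nrow(rois)), function(i) {
    cx <- rois$center_x[i]; cy <- rois$center_y[i]; cz <- rois$center_z[i]
    lo <- c(cx, cy, cz) - half
    hi <- c(cx, cy, cz) + half
    if (any(lo < 0) || any(hi >= dims))
      stop_ichwmi(sprintf("ROI '%s' extends outside the volume", rois$name[i]),
                  "ichwmi_roi_outside_error")
    block <- fa[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L]
    data.frame(name = rois$name[i], structure = rois$structure[i],
               side = rois$side[i], mean_fa = mean(block, na.rm = TRUE),
               n_inplane = extent^2, m_slices = extent,
               n_missing = sum(is.na(block)), pair = rois$pair[i])
  })
  res <- do.call(rbind, out)
  class(res) <- c("roi_stat", "data.frame")
  res
}

#' Right/left FA ratios over paired ROIs
#'
#' For every right-side ROI with a `pair` entry, the ratio of its mean FA
#' to its left partner's mean FA (right = ipsilateral to the injection in
#' the study protocol). Unpaired right ROIs raise an error; a zero left
#' mean yields `NA` with a flag.
#'
#' @param stats A [roi_mean_fa()] result.
#' @return Data frame: `name_right`, `name_left`, `structure`, `ratio`,
#'   `undefined`.
#' @export
fa_ratios <- function(stats) {
  right <- stats[stats$side == "right" & !is.na(stats$pair), , drop = FALSE]
  n_right_all <- sum(stats$side == "right")
  assert_that(nrow(right) == n_right_all,
              "every right ROI must name a left pair",
              class = "ichwmi_unpaired_roi_error")
  idx <- match(right$pair, stats$name)
  assert_that(!anyNA(idx), "pair names must exist in the ROI stats",
              class = "ichwmi_unpaired_roi_error")
  left <- stats[idx, , drop = FALSE]
  assert_that(all(left$side == "left") &&
                all(left$structure == right$structure),
              "pairs must be left-side ROIs of the same structure",
              class = "ichwmi_unpaired_roi_error")
  undefined <- left$mean_fa == 0 | is.na(left$mean_fa)
  ratio <- ifelse(undefined, NA_real_, right$mean_fa / left$mean_fa)
  data.frame(name_right = right$name, name_left = left$name,
             structure = right$structure, ratio = ratio,
             undefined = undefined, row.names = NULL)
}

#' Read / write DWI volumes and acquisition schemes
#'
#' NIfTI IO is delegated to RNifti; schemes use the FSL text dialect: a
#' `bvals` file with one row of b-values and a `bvecs` file with three rows
#' (x, y, z components, one column per volume).
#'
#' @param nii_path NIfTI path (`.nii` or `.nii.gz`).
#' @param bval_path,bvec_path FSL scheme file paths.
#' @param mask_path Optional NIfTI mask.
#' @return `read_dwi` returns a [dwi_volume()]; `read_scheme` a
#'   `diffusion_scheme`.
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path, mask_path = NULL) {
  img <- RNifti::readNifti(nii_path)
  scheme <- read_scheme(bval_path, bvec_path)
  mask <- if (!is.null(mask_path)) array(RNifti::readNifti(mask_path) > 0,
                                         dim = dim(img)[1:3])
  dwi_volume(array(as.numeric(img), dim = dim(img)), scheme, mask)
}

#' @rdname read_dwi
#' @export
read_scheme <- function(bval_path, bvec_path) {
  b <- scan(bval_path, quiet = TRUE)
  g <- t(as.matrix(read.table(bvec_path)))
  assert_that(nrow(g) == length(b), "bvals/bvecs length mismatch")
  nz <- b > 0
  norms <- sqrt(rowSums(g[nz, , drop = FALSE]^2))
  g[nz, ] <- g[nz, , drop = FALSE] / norms
  structure(list(b = b, g = g), class = "diffusion_scheme")
}

#' @rdname read_dwi
#' @param dwi A [dwi_volume()].
#' @export
write_dwi <- function(dwi, nii_path, bval_path, bvec_path) {
  RNifti::writeNifti(RNifti::asNifti(dwi$data), nii_path)
  write_scheme(dwi$scheme, bval_path, bvec_path)
  invisible(nii_path)
}

#' @rdname read_dwi
#' @param scheme A `diffusion_scheme`.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  cat(paste(scheme$b, collapse = " "), "\n", file = bval_path)
  write.table(t(scheme$g), bvec_path, row.names = FALSE, col.names = FALSE)
  invisible(bval_path)
}

#' @rdname read_dwi
#' @param fa An FA array; `path` the NIfTI destination.
#' @param path Output path.
#' @export
write_fa <- function(fa, path) {
  RNifti::writeNifti(RNifti::asNifti(unclass(fa)), path)
  invisible(path)
}

#' @rdname read_dwi
#' @export
read_fa <- function(path) {
  img <- RNifti::readNifti(path)
  structure(array(as.numeric(img), dim = dim(img)),
            class = c("fa_volume", "array"))
}
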