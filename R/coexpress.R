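#' Pick the soft-thresholding power for a scale-free network
#'
#' For each candidate power beta, forms the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta`, the connectivities `k_i = sum_{j != i}
#' a_ij`, and the signed scale-free topology fit: connectivities are binned
#' (10 equal-count-style breaks over the observed range), the log10 bin
#' frequency is regressed on the log10 bin mean connectivity, and R^2 is
#' negated when the slope is positive (a scale-free network has a falling
#' log-log degree distribution). The chosen power is the smallest candidate
#' whose signed R^2 reaches `r2_target`, or the argmax if none does.
#'
#' @param x An [expression_matrix()]; genes must be non-constant.
#' @param candidates Candidate integer powers.
#' @param r2_target Target signed R^2 (the study reports beta = 12 at
#'   R^2 = 0.86).
#' @param n_breaks Number of connectivity bins.
#' @return A list of class `soft_threshold_report`: `candidate_powers`,
#'   `fit_r2`, `mean_connectivity`, `chosen_power`.
#' @export
pick_soft_threshold <- function(x, candidates = c(1:10, seq(12, 20, 2)),
                                r2_target = 0.85, n_breaks = 10) {
  stopifnot(inherits(x, "expr_matrix"))
  assert_that(length(candidates) >= 1, "candidates must be non-empty")
  sds <- apply(x$values, 1, sd)
  assert_that(all(sds > 0),
              "constant gene rows have undefined correlation; prefilter first",
              class = "ichwmi_constant_gene_error")
  absr <- abs(cor(t(x$values)))
  diag(absr) <- 0
  fit_r2 <- numeric(length(candidates))
  mean_k <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    k <- rowSums(absr^candidates[i])
    mean_k[i] <- mean(k)
    fit_r2[i] <- scale_free_fit(k, n_breaks)
  }
  hit <- which(fit_r2 >= r2_target)
  chosen <- if (length(hit)) candidates[hit[1]] else candidates[which.max(fit_r2)]
  structure(list(candidate_powers = candidates, fit_r2 = fit_r2,
                 mean_connectivity = mean_k, chosen_power = chosen),
            class = "soft_threshold_report")
}

# Signed scale-free fit R^2 from a connectivity vector.
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  cuts <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = nlevels(cuts)) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  if (!is.na(slope) && slope > 0) -r2 else r2
}

#' Unsigned adjacency matrix at a given power
#'
#' @param x An [expression_matrix()].
#' @param power Soft-thresholding power beta.
#' @return Symmetric gene x gene matrix `|cor|^beta` with unit diagonal.
#' @export
adjacency_matrix <- function(x, power) {
  stopifnot(inherits(x, "expr_matrix"))
  a <- abs(cor(t(x$values)))^power
  dimnames(a) <- list(x$gene_ids, x$gene_ids)
  a
}

#' Topological overlap matrix from an adjacency matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for i != j, with unit diagonal, where `k_i` excludes the self-edge. The
#' TOM boosts the similarity of gene pairs that share network neighbours and
#' is the dissimilarity basis for module detection.
#'
#' @param a Symmetric adjacency with entries in `[0, 1]` (the diagonal is
#'   ignored and treated as the unit-diagonal convention internally).
#' @return Symmetric matrix of class `tom_matrix` with entries in `[0, 1]`
#'   and unit diagonal.
#' @export
tom_from_adjacency <- function(a) {
  assert_that(is.matrix(a) && nrow(a) == ncol(a) &&
                isTRUE(all.equal(a, t(a), tolerance = 1e-12)),
              "adjacency must be symmetric")
  assert_that(all(a >= 0 & a <= 1), "adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  shared <- a0 %*% a0 # (i,j): sum_u a_iu a_uj, u != i, j handled below
  numer <- shared + a0
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- numer / denom
  diag(tom) <- 1
  structure(pmin(pmax(tom, 0), 1), class = c("tom_matrix", "matrix"))
}

# First principal component of a module over samples: unit-norm per-sample
# vector, sign fixed so its mean correlation with the module genes is >= 0.
module_eigengene <- function(vals) {
  centered <- t(vals) - colMeans(t(vals)) # samples x genes, centered per gene
  sv <- svd(centered, nu = 1, nv = 0)
  me <- sv$u[, 1]
  cors <- suppressWarnings(cor(me, centered))
  if (mean(cors, na.rm = TRUE) < 0) me <- -me
  list(me = me, variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a static tree cut, assignment of clusters smaller than
#' `min_module_size` to the unassigned module 0 ("grey"), a quality gate
#' dropping clusters whose eigengene explains too little of their variance,
#' and iterative merging of modules whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` falls below `merge_cut_height`. Eigengenes are
#' recomputed after every merge, and genes only weakly correlated with
#' their final eigengene are returned to grey. The study parameters are
#' `min_module_size = 80` and `merge_cut_height = 0.20`.
#'
#' When `cut_height` is not given it is selected from the dendrogram
#' itself: over a grid of merge-height quantiles, the highest height that
#' maximises the number of clusters reaching `min_module_size` is used.
#' This keeps distinct modules from fusing when loosely attached background
#' genes join the tree above the inter-module merges, while letting each
#' module assemble fully before the kME cleanup strips the stragglers.
#'
#' @param tom A [tom_from_adjacency()] result (or any symmetric similarity
#'   in `[0, 1]` with unit diagonal).
#' @param x The [expression_matrix()] the TOM was built from (needed for
#'   eigengenes); gene order must match the TOM.
#' @param min_module_size Minimum module size (default 80).
#' @param merge_cut_height Eigengene-dissimilarity threshold below which
#'   modules merge (default 0.20).
#' @param cut_height Static cut height; `NULL` (default) selects it
#'   adaptively as described above.
#' @param min_kme After cutting and merging, genes whose absolute
#'   correlation with their module's eigengene falls below this value are
#'   returned to the unassigned module (guards against background genes
#'   absorbed by a static cut). Default 0.6; set to 0 to disable.
#' @param min_var_explained A cluster only counts as a module if its
#'   eigengene explains at least this fraction of the cluster's variance
#'   (default 0.25); screens out incoherent clusters cut from pure noise.
#' @return A list of class `module_assignment`: `module_id` (integer per
#'   gene, 0 = unassigned), `module_sizes`, `eigengenes` (samples x modules
#'   matrix of unit-norm MEs), `variance_explained`, `parameters`.
#' @export
detect_modules <- function(tom, x, min_module_size = 80,
                           merge_cut_height = 0.20, cut_height = NULL,
                           min_kme = 0.6, min_var_explained = 0.25) {
  stopifnot(inherits(x, "expr_matrix"))
  n <- nrow(tom)
  assert_that(n == nrow(x$values), "TOM and expression dimensions differ")
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(empty_assignment(x, min_module_size, merge_cut_height))
  }
  tree <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    heights <- unique(quantile(tree$height, seq(0.5, 0.995, by = 0.005)))
    n_big <- vapply(heights, function(h)
      sum(table(cutree(tree, h = h)) >= min_module_size), integer(1))
    # ties: highest such cut, so modules are fully assembled before the
    # kME cleanup strips loosely attached background genes
    cut_height <- heights[max(which(n_big == max(n_big)))]
  }
  raw <- cutree(tree, h = cut_height)
  # enforce minimum size and eigengene coherence
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  keep <- keep[vapply(keep, function(cl)
    module_eigengene(x$values[raw == cl, , drop = FALSE])$variance_explained >=
      min_var_explained, logical(1))]
  labels <- integer(n)
  for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  if (!any(labels > 0)) {
    warning("no coherent cluster reached min_module_size; all genes unassigned")
    return(empty_assignment(x, min_module_size, merge_cut_height))
  }
  # iterative eigengene merging
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    mes <- lapply(mods, function(m)
      module_eigengene(x$values[labels == m, , drop = FALSE]))
    me_mat <- vapply(mes, `[[`, numeric(ncol(x$values)), "me")
    if (length(mods) < 2) break
    d <- 1 - cor(me_mat)
    diag(d) <- Inf
    if (min(d) >= merge_cut_height) break
    pair <- which(d == min(d), arr.ind = TRUE)[1, ]
    labels[labels == mods[max(pair)]] <- mods[min(pair)]
  }
  # kME cleanup: drop weakly attached genes, then re-enforce minimum size
  if (min_kme > 0) {
    mods <- sort(unique(labels[labels > 0]))
    for (m in mods) {
      rows <- which(labels == m)
      me <- module_eigengene(x$values[rows, , drop = FALSE])$me
      kme <- suppressWarnings(abs(as.numeric(
        cor(t(x$values[rows, , drop = FALSE]), me))))
      kme[is.na(kme)] <- 0
      labels[rows[kme < min_kme]] <- 0L
      if (sum(labels == m) < min_module_size) labels[labels == m] <- 0L
    }
    if (!any(labels > 0)) {
      warning("no module survived the kME cleanup; all genes unassigned")
      return(empty_assignment(x, min_module_size, merge_cut_height))
    }
  }
  # relabel 1..K by decreasing size (module 1 = largest), grey stays 0
  mods <- sort(unique(labels[labels > 0]))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  new_id <- integer(max(mods))
  new_id[mods[order(-sizes)]] <- seq_along(mods)
  labels[labels > 0] <- new_id[labels[labels > 0]]
  mods <- seq_along(sizes)
  mes <- lapply(mods, function(m)
    module_eigengene(x$values[labels == m, , drop = FALSE]))
  me_mat <- vapply(mes, `[[`, numeric(ncol(x$values)), "me")
  colnames(me_mat) <- paste0("ME", mods)
  rownames(me_mat) <- x$sample_ids
  structure(list(
    module_id = stats::setNames(labels, x$gene_ids),
    module_sizes = stats::setNames(vapply(mods, function(m) sum(labels == m),
                                          integer(1)), paste0("ME", mods)),
    eigengenes = me_mat,
    variance_explained = vapply(mes, `[[`, numeric(1), "variance_explained"),
    parameters = list(min_module_size = min_module_size,
                      merge_cut_height = merge_cut_height,
                      cut_height = unname(cut_height))),
    class = "module_assignment")
}

empty_assignment <- function(x, min_module_size, merge_cut_height) {
  structure(list(
    module_id = stats::setNames(integer(nrow(x$values)), x$gene_ids),
    module_sizes = stats::setNames(integer(0), character(0)),
    eigengenes = matrix(numeric(0), nrow = ncol(x$values), ncol = 0,
                        dimnames = list(x$sample_ids, NULL)),
    variance_explained = numeric(0),
    parameters = list(min_module_size = min_module_size,
                      merge_cut_height = merge_cut_height,
                      cut_height = NA_real_)),
    class = "module_assignment")
}

# Two-sided p-value of a Pearson correlation via the exact t transform.
cor_test_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 2)
}

#' Module-trait correlation matrix
#'
#' Pearson correlation of every module eigengene with every numeric trait,
#' with the two-sided p-value from the t transform on n - 2 degrees of
#' freedom.
#'
#' @param assignment A [detect_modules()] result (or any samples x modules
#'   eigengene matrix).
#' @param traits Numeric vector or samples x traits matrix.
#' @return List with matrices `correlation` and `p` (modules x traits).
#' @export
module_trait_correlation <- function(assignment, traits) {
  me <- if (inherits(assignment, "module_assignment")) assignment$eigengenes
        else as.matrix(assignment)
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  assert_that(nrow(traits) == nrow(me),
              "trait length must equal the number of samples")
  assert_that(all(apply(traits, 2, sd) > 0),
              "zero-variance trait has undefined correlation",
              class = "ichwmi_undefined_correlation_error")
  r <- cor(me, traits)
  p <- cor_test_p(r, nrow(me))
  dimnames(p) <- dimnames(r)
  list(correlation = r, p = p)
}

#' Module membership and gene significance
#'
#' For each gene of the chosen module: MM is the Pearson correlation of the
#' gene's profile with the module eigengene; GS is `-log10 p` of the
#' gene-trait Pearson correlation test. Genes with constant expression are
#' reported as missing.
#'
#' @param x An [expression_matrix()].
#' @param assignment A [detect_modules()] result.
#' @param module Module id (integer, as in `assignment$module_id`).
#' @param trait Numeric trait per sample.
#' @param log_base Base of the GS logarithm (default 10).
#' @return Data frame of class `gene_module_stats` with columns `gene_id`,
#'   `mm`, `gs`.
#' @export
gene_mm_gs <- function(x, assignment, module, trait, log_base = 10) {
  stopifnot(inherits(x, "expr_matrix"),
            inherits(assignment, "module_assignment"))
  assert_that(module %in% assignment$module_id, "module not present")
  genes <- names(assignment$module_id)[assignment$module_id == module]
  me <- assignment$eigengenes[, paste0("ME", module)]
  n <- ncol(x$values)
  sub <- x$values[genes, , drop = FALSE]
  const <- apply(sub, 1, sd) == 0
  mm <- gs <- rep(NA_real_, length(genes))
  if (any(!const)) {
    mm[!const] <- as.numeric(cor(t(sub[!const, , drop = FALSE]), me))
    r_tr <- as.numeric(cor(t(sub[!const, , drop = FALSE]), trait))
    gs[!const] <- -log(cor_test_p(r_tr, n), base = log_base)
  }
  structure(data.frame(gene_id = genes, mm = mm, gs = gs),
            class = c("gene_module_stats", "data.frame"))
}

#' Select interesting genes by MM and GS thresholds
#'
#' Genes exceeding both thresholds strictly (`mm > mm_thr` and
#' `gs > gs_thr`) are retained; the study thresholds are MM > 0.9 and
#' GS > 0.85.
#'
#' @param stats A [gene_mm_gs()] result.
#' @param mm_thr Module-membership threshold (default 0.9).
#' @param gs_thr Gene-significance threshold (default 0.85).
#' @return A [gene_set()] labelled `"interesting"`.
#' @export
select_interesting <- function(stats, mm_thr = 0.9, gs_thr = 0.85) {
  keep <- !is.na(stats$mm) & !is.na(stats$gs) &
    stats$mm > mm_thr & stats$gs > gs_thr
  gene_set(stats$gene_id[keep], label = "interesting")
}
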