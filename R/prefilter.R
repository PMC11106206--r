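#' Pooled within-group variance per gene
#'
#' Scores each gene by its pooled within-group variance
#' `sum_g sum_{i in g} (x_i - xbar_g)^2 / (N - G)` over the `N` samples and
#' `G` groups. Genes with minimal scores are treated as background noise for
#' network construction and are the removal candidates of [apply_filter()].
#'
#' @param x An [expression_matrix()]; every group must have >= 2 samples.
#' @return Named numeric vector of per-gene scores.
#' @export
within_group_variance <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  groups <- x$sample_groups
  tab <- table(groups)
  assert_that(all(tab >= 2),
              "every group needs >= 2 samples for a within-group variance",
              class = "ichwmi_degenerate_group_error")
  n <- ncol(x$values)
  g <- length(tab)
  ss <- 0
  for (lab in names(tab)) {
    sub <- x$values[, groups == lab, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  ss / (n - g)
}

#' Leave-one-out SVM evaluation of group separability
#'
#' Trains, for each sample i, a linear support-vector classifier on the
#' remaining m - 1 samples (restricted to `gene_subset`) and predicts sample
#' i. Accuracy is the fraction of folds whose prediction matches the truth.
#' The F1 score is computed from true-positive / false-negative /
#' false-positive counts for `positive_class`; because each fold holds out a
#' single sample, the per-fold F1 is undefined (0/0) whenever a negative
#' sample is predicted correctly, so by default the counts are pooled across
#' folds before forming F1 (`mode = "pooled"`). `mode = "per_fold"` instead
#' averages per-fold F1 with the convention 0/0 -> 1.
#'
#' Features are standardised on each training fold (training statistics are
#' applied to the held-out sample); the SVM uses a linear kernel with unit
#' cost and has no internal randomness, so the evaluation is deterministic.
#'
#' @param x An [expression_matrix()] with >= 2 distinct groups.
#' @param gene_subset Gene identifiers to use as features (default: all).
#' @param positive_class Label counted as positive for F1 (default: first
#'   group level).
#' @param mode `"pooled"` (default) or `"per_fold"`.
#' @param cost SVM regularisation constant (default 1).
#' @return A list of class `loo_eval`: `m`, `predictions`, `truths`, `tp`,
#'   `fn`, `fp`, `accuracy`, `f1`, `n_failed_folds`.
#' @export
loo_svm_eval <- function(x, gene_subset = x$gene_ids,
                         positive_class = unique(x$sample_groups)[1],
                         mode = c("pooled", "per_fold"), cost = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  assert_that(length(gene_subset) >= 1, "gene_subset must be non-empty")
  assert_that(length(unique(x$sample_groups)) >= 2,
              ">= 2 groups required for supervised evaluation")
  feats <- t(x$values[gene_subset, , drop = FALSE]) # samples x genes
  truth <- factor(x$sample_groups)
  m <- nrow(feats)
  preds <- character(m)
  failed <- 0L
  for (i in seq_len(m)) {
    tr <- feats[-i, , drop = FALSE]
    y <- droplevels(truth[-i])
    if (nlevels(y) < 2) {
      preds[i] <- NA_character_
      failed <- failed + 1L
      next
    }
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, sd)
    sdv[sdv == 0] <- 1
    trs <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
    tes <- (feats[i, ] - mu) / sdv
    fit <- e1071::svm(trs, y, kernel = "linear", cost = cost, scale = FALSE)
    preds[i] <- as.character(predict(fit, matrix(tes, nrow = 1)))
  }
  truths <- as.character(truth)
  ok <- !is.na(preds)
  accuracy <- sum(preds[ok] == truths[ok]) / m
  tp <- sum(ok & preds == positive_class & truths == positive_class)
  fp <- sum(ok & preds == positive_class & truths != positive_class)
  fn <- sum(ok & preds != positive_class & truths == positive_class)
  f1 <- if (mode == "pooled") {
    if (2 * tp + fn + fp == 0) 1 else 2 * tp / (2 * tp + fn + fp)
  } else {
    per <- vapply(which(ok), function(i) {
      tpi <- as.numeric(preds[i] == positive_class & truths[i] == positive_class)
      fpi <- as.numeric(preds[i] == positive_class & truths[i] != positive_class)
      fni <- as.numeric(preds[i] != positive_class & truths[i] == positive_class)
      if (2 * tpi + fni + fpi == 0) 1 else 2 * tpi / (2 * tpi + fni + fpi)
    }, numeric(1))
    sum(per) / m
  }
  structure(list(m = m, predictions = preds, truths = truths,
                 tp = tp, fn = fn, fp = fp, accuracy = accuracy, f1 = f1,
                 n_failed_folds = failed),
            class = "loo_eval")
}

#' Sweep removal fractions and evaluate the classifier on the remainder
#'
#' For each fraction, removes that fraction of lowest-variance genes (per
#' [within_group_variance()]) and reports the leave-one-out SVM accuracy and
#' F1 on the remaining genes. A row for fraction 0 (no filtering) is always
#' included.
#'
#' @param x An [expression_matrix()].
#' @param fractions Ascending removal fractions in `[0, 1)`.
#' @param ... Passed to [loo_svm_eval()].
#' @return Data frame with columns `fraction`, `n_kept`, `accuracy`, `f1`.
#' @export
filter_sweep <- function(x, fractions = seq(0, 0.5, by = 0.1), ...) {
  assert_that(!is.unsorted(fractions), "fractions must be sorted ascending")
  assert_that(all(fractions < 1), "fraction 1 would leave no genes",
              class = "ichwmi_empty_geneset_error")
  fractions <- unique(c(0, fractions))
  rows <- lapply(fractions, function(f) {
    kept <- apply_filter(x, f)$kept_gene_ids
    ev <- loo_svm_eval(x, kept, ...)
    data.frame(fraction = f, n_kept = length(kept),
               accuracy = ev$accuracy, f1 = ev$f1)
  })
  do.call(rbind, rows)
}

#' Remove the lowest-variance fraction of genes
#'
#' Removes exactly `floor(fraction * n_genes)` genes with the smallest
#' pooled within-group variance; ties are broken by gene identifier
#' (lexicographic), so the result is deterministic. The study setting is
#' `fraction = 0.30`.
#'
#' @param x An [expression_matrix()].
#' @param fraction Removal fraction in `[0, 1)`.
#' @return A list of class `filter_result`: `kept_gene_ids`,
#'   `removed_gene_ids`, `removed_fraction`, `variance_scores`.
#' @export
apply_filter <- function(x, fraction = 0.30) {
  stopifnot(inherits(x, "expr_matrix"))
  assert_that(fraction >= 0 && fraction < 1, "fraction must lie in [0, 1)")
  scores <- within_group_variance(x)
  n_remove <- floor(fraction * length(scores))
  ord <- order(scores, x$gene_ids) # ascending variance, gene id tiebreak
  removed <- x$gene_ids[ord[seq_len(n_remove)]]
  kept <- setdiff(x$gene_ids, removed)
  structure(list(kept_gene_ids = kept, removed_gene_ids = removed,
                 removed_fraction = fraction, variance_scores = scores),
            class = "filter_result")
}
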