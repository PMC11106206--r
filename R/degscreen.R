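#' Per-gene two-sample differential-expression test
#'
#' For every gene, a pooled-variance two-sample t statistic between
#' `group_a` and `group_b` with the two-sided p-value from the t
#' distribution, Benjamini-Hochberg q-values over all tested genes, and
#' fold changes. Expression is assumed log2-scale, so
#' `log2fc = mean_a - mean_b` and the linear fold change is `2^log2fc`,
#' reported with the microarray sign convention: ratios below 1 are
#' reported as `-1 / ratio` (so halving is -2, doubling is +2).
#'
#' Genes with zero pooled variance are flagged and given the conventional
#' p-value 0 when the group means differ and 1 otherwise.
#'
#' @param x An [expression_matrix()].
#' @param group_a,group_b Group labels to compare (each with >= 2 samples).
#' @param welch Use Welch's unequal-variance t test instead of the pooled
#'   test (default `FALSE`).
#' @return Data frame of class `deg_table` with columns `gene_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `fold_change`, `t_stat`, `p`, `q`,
#'   `zero_variance`.
#' @export
deg_test <- function(x, group_a, group_b, welch = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  ia <- x$sample_groups == group_a
  ib <- x$sample_groups == group_b
  na <- sum(ia); nb <- sum(ib)
  assert_that(na >= 2 && nb >= 2, "both groups need >= 2 samples")
  xa <- x$values[, ia, drop = FALSE]
  xb <- x$values[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  }
  zerovar <- se2 == 0
  t_stat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(t_stat), df = df)
  t_stat[zerovar] <- ifelse(ma[zerovar] == mb[zerovar], 0, Inf * sign(ma - mb)[zerovar])
  p[zerovar] <- ifelse(ma[zerovar] == mb[zerovar], 1, 0)
  if (any(zerovar))
    warning(sum(zerovar), " gene(s) with zero pooled variance; p set by convention")
  q <- p.adjust(p, method = "BH")
  log2fc <- ma - mb
  ratio <- 2^log2fc
  fold_change <- ifelse(ratio >= 1, ratio, -1 / ratio)
  structure(data.frame(gene_id = x$gene_ids, mean_a = ma, mean_b = mb,
                       log2fc = log2fc, fold_change = fold_change,
                       t_stat = t_stat, p = p, q = q,
                       zero_variance = zerovar, row.names = NULL),
            class = c("deg_table", "data.frame"))
}

#' Gene set with case-normalised unique members
#'
#' @param members Character vector of gene identifiers; whitespace is
#'   stripped and identifiers upper-cased before deduplication.
#' @param label Optional set label.
#' @return A list of class `gene_set` with `label` and sorted `members`.
#' @export
gene_set <- function(members, label = "") {
  members <- sort(unique(toupper(trimws(as.character(members)))))
  members <- members[nzchar(members)]
  structure(list(label = label, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> %d genes: %s\n", x$label, length(x$members),
              paste(head(x$members, 8), collapse = ", ")))
  invisible(x)
}

#' Threshold a DEG table into a gene set
#'
#' Keeps genes with `|fold_change| > fc_thr` and `q < fdr_thr`, both
#' strictly; the study thresholds are fold change > 2 (or < -2) and BH FDR
#' 0.05.
#'
#' @param tab A [deg_test()] table.
#' @param fc_thr Linear fold-change threshold (default 2).
#' @param fdr_thr BH q-value threshold (default 0.05).
#' @param label Label for the resulting set.
#' @return A [gene_set()].
#' @export
filter_degs <- function(tab, fc_thr = 2, fdr_thr = 0.05, label = "DEGs") {
  assert_that(fc_thr > 0 && fdr_thr > 0, "thresholds must be positive")
  keep <- abs(tab$fold_change) > fc_thr & tab$q < fdr_thr
  gene_set(tab$gene_id[keep], label = label)
}

#' Intersect gene sets
#'
#' Exact case-normalised intersection; output members sorted
#' lexicographically.
#'
#' @param sets List of [gene_set()]s (>= 2).
#' @param label Label for the result.
#' @return A [gene_set()].
#' @export
intersect_sets <- function(sets, label = "intersection") {
  assert_that(is.list(sets) && length(sets) >= 2,
              ">= 2 gene sets required for an intersection")
  members <- Reduce(intersect, lapply(sets, function(s) gene_set(s$members)$members))
  gene_set(members, label = label)
}

#' Two-stage candidate/finalist screening funnel
#'
#' Stage 1 intersects the two DEG sets (tissue dataset and blood dataset)
#' into the candidate genes; stage 2 intersects the candidates with the
#' network-derived interesting genes into the finalists. In the study this
#' funnel reduces 1105 and 125 DEGs to 8 candidates and then, against 94
#' interesting genes, to the 3 finalists CMTM5, COL9A2 and SLC45A3.
#'
#' @param interesting [gene_set()] from [select_interesting()].
#' @param degs_tissue,degs_blood [gene_set()]s of DEGs from the two
#'   datasets.
#' @return A list of class `screen_funnel` with per-stage sets and counts.
#' @export
screen_funnel <- function(interesting, degs_tissue, degs_blood) {
  candidates <- intersect_sets(list(degs_tissue, degs_blood),
                               label = "candidates")
  finalists <- intersect_sets(list(candidates, interesting),
                              label = "finalists")
  structure(list(
    stages = list(
      interesting = interesting, degs_tissue = degs_tissue,
      degs_blood = degs_blood, candidates = candidates,
      finalists = finalists),
    counts = c(interesting = length(interesting$members),
               degs_tissue = length(degs_tissue$members),
               degs_blood = length(degs_blood$members),
               candidates = length(candidates$members),
               finalists = length(finalists$members))),
    class = "screen_funnel")
}

#' @export
print.screen_funnel <- function(x, ...) {
  cat("<screen_funnel>\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %d\n", nm, x$counts[[nm]]))
  fin <- x$stages$finalists$members
  shown <- paste(head(fin, 8), collapse = ", ")
  if (length(fin) > 8) shown <- paste0(shown, ", ... (", length(fin), " total)")
  cat("  finalists:", shown, "\n")
  invisible(x)
}
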