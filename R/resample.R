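#' Percentile bootstrap confidence interval for a mean
#'
#' Draws `n_resample` with-replacement resamples of the input, takes the
#' mean of each, and reports the empirical `(1 - level)/2` and
#' `1 - (1 - level)/2` percentiles of the resample means. The study
#' summarises every FA subgroup this way, with 10,000 resamples at the 95%
#' level.
#'
#' @param values Numeric sample (>= 2 values).
#' @param level Nominal coverage in `(0, 1)` (default 0.95).
#' @param n_resample Number of resamples (default 10000).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A list of class `bootstrap_result`: `point_estimate`, `level`,
#'   `n_resample`, `ci_low`, `ci_high`, `seed`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_resample = 10000, seed = 1L) {
  assert_that(length(values) >= 2, "need >= 2 values to resample",
              class = "ichwmi_degenerate_sample_error")
  assert_that(level > 0 && level < 1, "level must lie in (0, 1)")
  n <- length(values)
  means <- with_local_seed(seed, {
    idx <- sample.int(n, n * n_resample, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n, ncol = n_resample))
  })
  # (R+1)*alpha order-statistic convention for the percentile endpoints
  qs <- unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 6))
  structure(list(point_estimate = mean(values), level = level,
                 n_resample = n_resample, ci_low = qs[1], ci_high = qs[2],
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

# Number of distinct two-group label arrangements.
n_arrangements_2 <- function(na, nb) choose(na + nb, na)

#' Fisher-Pitman two-sample permutation test
#'
#' Tests equality of location between two samples by relabeling the pooled
#' observations. The statistic is the absolute difference of group means;
#' the two-sided p-value is the fraction of arrangements whose statistic is
#' at least the observed one. Exact mode enumerates all
#' `choose(n_a + n_b, n_a)` relabelings (the default when that count is at
#' most `exact_threshold`); Monte-Carlo mode draws `n_resample` random
#' relabelings and uses the add-one estimator
#' `p = (1 + #{>= observed}) / (1 + n_resample)`, which counts the observed
#' arrangement and can never return zero.
#'
#' @param a,b Numeric samples (non-empty).
#' @param n_resample Monte-Carlo resamples (default 10000, the study
#'   setting).
#' @param mode `"auto"` (exact when feasible), `"exact"`, or
#'   `"monte_carlo"`.
#' @param seed Integer seed (Monte-Carlo mode only).
#' @param exact_threshold Max arrangements for auto-exact (default 1e5).
#' @return A list of class `permutation_result`: `statistic`, `p`, `mode`,
#'   `n_resample` or `n_total_arrangements`, `seed`, `degenerate`.
#' @export
fisher_pitman_2sample <- function(a, b, n_resample = 10000,
                                  mode = c("auto", "exact", "monte_carlo"),
                                  seed = 1L, exact_threshold = 1e5) {
  mode <- match.arg(mode)
  assert_that(length(a) >= 1 && length(b) >= 1, "both samples must be non-empty")
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  obs <- abs(mean(a) - mean(b))
  if (all(pooled == pooled[1])) {
    return(structure(list(statistic = 0, p = 1, mode = "degenerate",
                          n_total_arrangements = n_arrangements_2(na, nb),
                          n_resample = NA_integer_, seed = as.integer(seed),
                          degenerate = TRUE),
                     class = "permutation_result"))
  }
  total <- n_arrangements_2(na, nb)
  use_exact <- mode == "exact" || (mode == "auto" && total <= exact_threshold)
  eps <- 1e-12 * max(1, obs)
  if (use_exact) {
    tot_sum <- sum(pooled)
    n_tot <- na + nb
    combs <- combn(n_tot, na)
    stats <- abs(colSums(matrix(pooled[combs], nrow = na)) / na -
                   (tot_sum - colSums(matrix(pooled[combs], nrow = na))) / nb)
    p <- sum(stats >= obs - eps) / total
    structure(list(statistic = obs, p = p, mode = "exact",
                   n_total_arrangements = total, n_resample = NA_integer_,
                   seed = as.integer(seed), degenerate = FALSE),
              class = "permutation_result")
  } else {
    count <- with_local_seed(seed, {
      hits <- 0L
      for (r in seq_len(n_resample)) {
        perm <- sample(pooled)
        s <- abs(mean(perm[seq_len(na)]) - mean(perm[na + seq_len(nb)]))
        if (s >= obs - eps) hits <- hits + 1L
      }
      hits
    })
    structure(list(statistic = obs, p = (1 + count) / (1 + n_resample),
                   mode = "monte_carlo", n_total_arrangements = total,
                   n_resample = n_resample, seed = as.integer(seed),
                   degenerate = FALSE),
              class = "permutation_result")
  }
}

#' Fisher-Pitman k-sample permutation test
#'
#' Omnibus test across k groups with the permutation-ANOVA between-group
#' sum of squares `sum_g n_g (mean_g - grand_mean)^2` as statistic; the
#' null distribution permutes group labels over the pooled observations.
#' Exact when the number of distinct arrangements is at most
#' `exact_threshold`, otherwise Monte Carlo with the add-one estimator.
#'
#' @param samples List of k >= 2 non-empty numeric samples.
#' @inheritParams fisher_pitman_2sample
#' @return A `permutation_result` (upper-tail p).
#' @export
fisher_pitman_ksample <- function(samples, n_resample = 10000,
                                  mode = c("auto", "exact", "monte_carlo"),
                                  seed = 1L, exact_threshold = 1e5) {
  mode <- match.arg(mode)
  assert_that(is.list(samples) && length(samples) >= 2,
              "need >= 2 samples")
  assert_that(all(lengths(samples) >= 1), "all samples must be non-empty")
  ns <- lengths(samples)
  pooled <- unlist(samples, use.names = FALSE)
  k <- length(samples)
  ssb <- function(v) {
    grand <- mean(v)
    idx <- 0
    s <- 0
    for (g in seq_len(k)) {
      mg <- mean(v[idx + seq_len(ns[g])])
      s <- s + ns[g] * (mg - grand)^2
      idx <- idx + ns[g]
    }
    s
  }
  obs <- ssb(pooled)
  if (all(pooled == pooled[1])) {
    return(structure(list(statistic = 0, p = 1, mode = "degenerate",
                          n_total_arrangements = NA_real_,
                          n_resample = NA_integer_, seed = as.integer(seed),
                          degenerate = TRUE),
                     class = "permutation_result"))
  }
  total <- factorial(sum(ns)) / prod(factorial(ns))
  use_exact <- mode == "exact" || (mode == "auto" && total <= exact_threshold)
  eps <- 1e-12 * max(1, obs)
  if (use_exact) {
    arr <- enumerate_assignments(ns)
    stats <- vapply(arr, function(ordering) ssb(pooled[ordering]), numeric(1))
    p <- sum(stats >= obs - eps) / length(arr)
    structure(list(statistic = obs, p = p, mode = "exact",
                   n_total_arrangements = length(arr),
                   n_resample = NA_integer_, seed = as.integer(seed),
                   degenerate = FALSE),
              class = "permutation_result")
  } else {
    count <- with_local_seed(seed, {
      hits <- 0L
      for (r in seq_len(n_resample)) {
        if (ssb(sample(pooled)) >= obs - eps) hits <- hits + 1L
      }
      hits
    })
    structure(list(statistic = obs, p = (1 + count) / (1 + n_resample),
                   mode = "monte_carlo", n_total_arrangements = total,
                   n_resample = n_resample, seed = as.integer(seed),
                   degenerate = FALSE),
              class = "permutation_result")
  }
}

# Enumerate all distinct assignments of pooled indices to ordered groups of
# sizes `ns`. Returns a list of index orderings (group 1 first, ...).
enumerate_assignments <- function(ns) {
  n <- sum(ns)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1) return(list(avail))
    picks <- combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(avail, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  rec(seq_len(n), ns)
}

#' Subgroup design for the omnibus-then-pairwise comparison
#'
#' The study design crosses 3 experimental arms (sham, ICH + control
#' vector, ICH + SLC45A3 vector) with 6 FA measures (right/left/ratio x
#' CC/IC), giving 18 subgroup cells.
#'
#' @param cells Named list: `cells[[measure]][[group]]` is the numeric
#'   vector of values for that subgroup.
#' @return A list of class `subgroup_design` with `groups`, `measures`,
#'   `cells`, `n_cells`.
#' @export
subgroup_design <- function(cells) {
  assert_that(is.list(cells) && length(cells) >= 1, "cells must be a list")
  measures <- names(cells)
  groups <- unique(unlist(lapply(cells, names)))
  for (m in measures)
    assert_that(identical(sort(names(cells[[m]])), sort(groups)),
                "every measure needs the same group set")
  structure(list(groups = groups, measures = measures, cells = cells,
                 n_cells = length(groups) * length(measures)),
            class = "subgroup_design")
}

#' Omnibus-then-pairwise gatekeeping comparisons
#'
#' Per measure: a k-sample Fisher-Pitman omnibus test across all groups;
#' only if its p-value is below `alpha` are the pairwise two-sample tests
#' computed, each reported with the direction of the observed difference
#' (+1 when the first group's mean is higher). Bootstrap CIs are attached
#' to every cell. No multiplicity correction is applied across cells or
#' pairs by default, mirroring uncorrected post-hoc reporting; BH over the
#' pairwise p-values is available via `adjust = "BH"`.
#'
#' @param design A [subgroup_design()].
#' @param alpha Gate level (default 0.05).
#' @param n_resample Resamples for permutation tests and bootstrap.
#' @param seed Integer master seed (per-test seeds are derived by fixed
#'   offsets).
#' @param mode Permutation mode passed through.
#' @param adjust `"none"` (default) or `"BH"` over pairwise p-values
#'   within a measure.
#' @return A list of class `gatekeeping_report`: per measure the omnibus
#'   `permutation_result`, a data frame of pairwise results (or marker
#'   `tested = FALSE`), and per-cell bootstrap CIs.
#' @export
gatekeeping_compare <- function(design, alpha = 0.05, n_resample = 10000,
                                seed = 1L, mode = "auto",
                                adjust = c("none", "BH")) {
  stopifnot(inherits(design, "subgroup_design"))
  adjust <- match.arg(adjust)
  assert_that(length(design$groups) >= 2, ">= 2 groups per measure required")
  seed <- as.integer(seed)
  report <- list()
  offset <- 0L
  for (m in design$measures) {
    cell <- design$cells[[m]][design$groups]
    omnibus <- fisher_pitman_ksample(cell, n_resample = n_resample,
                                     mode = mode, seed = seed + offset)
    offset <- offset + 1L
    cis <- lapply(design$groups, function(g) {
      offset <<- offset + 1L
      bootstrap_ci(cell[[g]], n_resample = n_resample, seed = seed + offset)
    })
    names(cis) <- design$groups
    pairwise <- NULL
    if (omnibus$p < alpha) {
      combs <- combn(design$groups, 2, simplify = FALSE)
      rows <- lapply(combs, function(pr) {
        offset <<- offset + 1L
        res <- fisher_pitman_2sample(cell[[pr[1]]], cell[[pr[2]]],
                                     n_resample = n_resample, mode = mode,
                                     seed = seed + offset)
        data.frame(group_a = pr[1], group_b = pr[2], p = res$p,
                   statistic = res$statistic,
                   direction = sign(mean(cell[[pr[1]]]) - mean(cell[[pr[2]]])),
                   mode = res$mode)
      })
      pairwise <- do.call(rbind, rows)
      if (adjust == "BH") pairwise$p_adj <- p.adjust(pairwise$p, "BH")
    }
    report[[m]] <- list(omnibus = omnibus, tested = omnibus$p < alpha,
                        pairwise = pairwise, bootstrap = cis)
  }
  structure(list(measures = report, alpha = alpha,
                 groups = design$groups, n_cells = design$n_cells),
            class = "gatekeeping_report")
}
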