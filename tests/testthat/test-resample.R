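test_that("bootstrap CI basics: constancy, determinism, ordering, range", {
  cst <- bootstrap_ci(rep(3.5, 10), seed = 1)
  expect_equal(cst$ci_low, 3.5)
  expect_equal(cst$ci_high, 3.5)
  set.seed(61)
  v <- rnorm(15, 0.45, 0.05)
  b1 <- bootstrap_ci(v, seed = 9)
  b2 <- bootstrap_ci(v, seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)
  expect_gte(b1$ci_low, min(v))
  expect_lte(b1$ci_high, max(v))
  expect_error(bootstrap_ci(1), class = "ichwmi_degenerate_sample_error")
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(62)
  v100 <- rnorm(100)
  v10 <- v100[1:10]
  w10 <- with(bootstrap_ci(v10, seed = 5), ci_high - ci_low)
  w100 <- with(bootstrap_ci(v100, seed = 5), ci_high - ci_low)
  expect_lt(w100, w10)
})

test_that("two-sample exact permutation p matches full enumeration", {
  r <- fisher_pitman_2sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$mode, "exact")
  expect_equal(r$n_total_arrangements, 20)
  expect_equal(r$p, 0.1) # only the two extreme splits reach |dmean| = 3
  # same multiset -> statistic 0, p = 1
  r0 <- fisher_pitman_2sample(c(1, 2), c(2, 1))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # all identical -> degenerate flag
  rd <- fisher_pitman_2sample(c(2, 2), c(2, 2))
  expect_true(rd$degenerate)
  expect_equal(rd$p, 1)
})

test_that("Monte-Carlo p agrees with exact within 3 binomial SE on small cases", {
  set.seed(63)
  cases <- list(c(3, 3), c(4, 3), c(4, 4), c(5, 3), c(2, 6))
  for (sz in cases) {
    a <- rnorm(sz[1])
    b <- rnorm(sz[2], 1)
    ex <- fisher_pitman_2sample(a, b, mode = "exact")
    mc <- fisher_pitman_2sample(a, b, mode = "monte_carlo",
                                n_resample = 10000, seed = 101)
    se <- sqrt(ex$p * (1 - ex$p) / 10000)
    expect_lt(abs(mc$p - ex$p), 3 * se + 2 / 10001)
    expect_gte(mc$p, 1 / 10001) # add-one estimator never returns 0
  }
})

test_that("exact null distribution of p is uniform on the attainable grid", {
  # distinct values, n = 3 + 3: every arrangement's p must be k/20 and the
  # ECDF of p over all arrangements must satisfy P(p <= t) <= t at grid points
  vals <- c(0.3, 1.1, 2.7, 3.4, 5.9, 8.1)
  combs <- combn(6, 3)
  ps <- apply(combs, 2, function(ix) {
    fisher_pitman_2sample(vals[ix], vals[-ix], mode = "exact")$p
  })
  expect_true(all(abs(ps * 20 - round(ps * 20)) < 1e-9))
  for (t in unique(ps)) expect_lte(mean(ps <= t), t + 1e-9)
})

test_that("k-sample test reduces to the two-sample test for k = 2", {
  set.seed(64)
  a <- rnorm(4)
  b <- rnorm(4, 1)
  p2 <- fisher_pitman_2sample(a, b, mode = "exact")$p
  pk <- fisher_pitman_ksample(list(a, b), mode = "exact")$p
  expect_equal(pk, p2)
})

test_that("k-sample omnibus: identical samples give p = 1; type-I error is controlled", {
  r <- fisher_pitman_ksample(list(c(1, 2), c(2, 1), c(1, 2)), mode = "exact")
  expect_equal(r$p, 1)
  # null calibration at n = 3 per group; exact enumeration per replicate
  set.seed(65)
  rej <- replicate(400, {
    s <- lapply(1:3, function(i) rnorm(3))
    fisher_pitman_ksample(s, mode = "exact")$p < 0.05
  })
  # binomial 3 SE band around 0.05 (exact permutation p is conservative)
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("subgroup design enumerates groups x measures cells", {
  cells <- list()
  for (m in c("FA_right_CC", "FA_left_CC", "FA_ratio_CC",
              "FA_right_IC", "FA_left_IC", "FA_ratio_IC")) {
    cells[[m]] <- list(sham = rnorm(3), ich = rnorm(3), slc = rnorm(3))
  }
  design <- subgroup_design(cells)
  expect_equal(design$n_cells, 18)
  expect_length(design$measures, 6)
  expect_length(design$groups, 3)
})

test_that("gatekeeping: omnibus gate controls pairwise testing and alpha is monotone", {
  set.seed(66)
  null_cells <- list(m1 = list(a = rnorm(4), b = rnorm(4), c = rnorm(4)))
  eff_cells <- list(m2 = list(a = rnorm(4), b = rnorm(4) + 5,
                              c = rnorm(4)))
  d_null <- subgroup_design(null_cells)
  d_eff <- subgroup_design(eff_cells)
  rep_null <- gatekeeping_compare(d_null, alpha = 0.05, n_resample = 500,
                                  seed = 1)
  if (!rep_null$measures$m1$tested)
    expect_null(rep_null$measures$m1$pairwise)
  rep_eff <- gatekeeping_compare(d_eff, alpha = 0.05, n_resample = 500,
                                 seed = 1)
  expect_true(rep_eff$measures$m2$tested)
  expect_equal(nrow(rep_eff$measures$m2$pairwise), 3)
  # direction: b has the higher mean
  pw <- rep_eff$measures$m2$pairwise
  expect_equal(pw$direction[pw$group_a == "a" & pw$group_b == "b"], -1)
  # lowering alpha never increases the number of pairwise tests
  rep_tiny <- gatekeeping_compare(d_eff, alpha = 1e-6, n_resample = 500,
                                  seed = 1)
  n_tests <- function(r) sum(vapply(r$measures, function(m)
    if (is.null(m$pairwise)) 0L else nrow(m$pairwise), integer(1)))
  expect_lte(n_tests(rep_tiny), n_tests(rep_eff))
})

test_that("gatekeeping localises a planted right-IC effect", {
  set.seed(67)
  mk <- function(ic_shift) {
    list(
      FA_right_CC = rnorm(10, 0.55, 0.02),
      FA_left_CC = rnorm(10, 0.55, 0.02),
      FA_right_IC = rnorm(10, 0.55 + ic_shift, 0.02),
      FA_left_IC = rnorm(10, 0.55, 0.02))
  }
  arms <- list(sham = mk(0), ich = mk(-0.15), slc = mk(-0.05))
  cells <- lapply(setNames(names(arms$sham), names(arms$sham)), function(m)
    lapply(arms, `[[`, m))
  rep <- gatekeeping_compare(subgroup_design(cells), alpha = 0.05,
                             n_resample = 2000, seed = 3)
  expect_true(rep$measures$FA_right_IC$tested)
  expect_false(rep$measures$FA_right_CC$tested)
  expect_false(rep$measures$FA_left_CC$tested)
  pw <- rep$measures$FA_right_IC$pairwise
  expect_lt(pw$p[pw$group_a == "sham" & pw$group_b == "ich"], 0.05)
})
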