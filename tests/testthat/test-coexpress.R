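test_that("power-1 adjacency is |r| and adjacency decreases with beta", {
  d <- benchmark_expression(seed = 2)
  x <- subset_genes_for_test(d$expr, 1:20)
  a1 <- adjacency_matrix(x, 1)
  expect_equal(unname(a1), unname(abs(cor(t(x$values)))))
  a6 <- adjacency_matrix(x, 6)
  off <- upper.tri(a1)
  expect_true(all(a6[off] <= a1[off] + 1e-15))
})

test_that("soft threshold pick is deterministic and R2 matches a re-fit", {
  d <- benchmark_expression(seed = 21)
  r1 <- pick_soft_threshold(d$expr, 1:8, 0.85)
  r2 <- pick_soft_threshold(d$expr, 1:8, 0.85)
  expect_identical(r1, r2)
  expect_true(r1$chosen_power %in% r1$candidate_powers)
  expect_true(all(abs(r1$fit_r2) <= 1 + 1e-12, na.rm = TRUE))
  # independent recomputation of the signed fit at one power
  beta <- 6
  absr <- abs(cor(t(d$expr$values)))
  diag(absr) <- 0
  k <- rowSums(absr^beta)
  cuts <- cut(k, breaks = 10)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = nlevels(cuts)) / length(k)
  keep <- !is.na(dk) & pk > 0
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2o <- summary(fit)$r.squared * ifelse(coef(fit)[2] > 0, -1, 1)
  expect_equal(r1$fit_r2[match(beta, r1$candidate_powers)], unname(r2o),
               tolerance = 1e-12)
})

test_that("constant genes are rejected before correlation", {
  vals <- rbind(rep(1, 6), matrix(rnorm(30), 5))
  x <- expression_matrix(vals, sample_groups = rep(c("a", "b"), each = 3))
  expect_error(pick_soft_threshold(x, 1:3),
               class = "ichwmi_constant_gene_error")
})

test_that("TOM equals the brute-force triple-loop oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n <- sample(4:8, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_from_adjacency(a)
    expect_equal(unname(unclass(tom)), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("TOM limit cases: perfect pair and empty network", {
  a <- diag(2)
  a[1, 2] <- a[2, 1] <- 1
  expect_equal(tom_from_adjacency(a)[1, 2], 1)
  z <- diag(3)
  expect_equal(unname(unclass(tom_from_adjacency(z))), diag(3))
  bad <- matrix(c(0, 1, 0, 0), 2)
  expect_error(tom_from_adjacency(bad), "symmetric")
})

test_that("planted modules are recovered with high ARI and correct count", {
  skip_if_not_installed("mclust")
  d <- benchmark_expression(seed = 7)
  tom <- tom_from_adjacency(adjacency_matrix(d$expr, 6))
  mods <- detect_modules(tom, d$expr, min_module_size = 80,
                         merge_cut_height = 0.20)
  expect_equal(length(mods$module_sizes), 3)
  ari <- mclust::adjustedRandIndex(d$truth$module_labels, mods$module_id)
  expect_gte(ari, 0.9)
  # determinism
  mods2 <- detect_modules(tom, d$expr, 80, 0.20)
  expect_identical(mods$module_id, mods2$module_id)
})

test_that("modules driven by one factor merge at cut height 0.20", {
  d <- gen_expression(synth_expression_spec(n_genes = 300,
    n_samples_per_group = 6, module_sizes = c(150, 150),
    within_module_cor = 0.8, seed = 3))
  v <- d$expr$values
  # rebuild the second module from the first module's factor
  v[151:300, ] <- v[1:150, ] + matrix(rnorm(150 * 12, sd = 0.3), 150)
  x <- expression_matrix(v, d$expr$gene_ids, d$expr$sample_ids,
                         d$expr$sample_groups)
  mods <- detect_modules(tom_from_adjacency(adjacency_matrix(x, 6)), x,
                         80, 0.20)
  expect_equal(length(mods$module_sizes), 1)
})

test_that("pure-noise matrices produce no modules", {
  d <- gen_expression(synth_expression_spec(n_genes = 300,
    n_samples_per_group = 6, module_sizes = integer(0), seed = 5))
  tom <- tom_from_adjacency(adjacency_matrix(d$expr, 6))
  expect_warning(mods <- detect_modules(tom, d$expr, 80, 0.20), "unassigned")
  expect_true(all(mods$module_id == 0))
})

test_that("eigengenes are unit-norm top principal directions", {
  d <- benchmark_expression(seed = 7)
  tom <- tom_from_adjacency(adjacency_matrix(d$expr, 6))
  mods <- detect_modules(tom, d$expr, 80, 0.20)
  me <- mods$eigengenes[, 1]
  expect_equal(sum(me^2), 1)
  genes <- names(mods$module_id)[mods$module_id == 1]
  centered <- t(d$expr$values[genes, ]) -
    colMeans(t(d$expr$values[genes, ]))
  # variance explained is maximal over random unit sample-vectors
  ve <- function(u) sum((t(centered) %*% u)^2) / sum(centered^2)
  set.seed(77)
  rand_ve <- replicate(100, {
    u <- rnorm(length(me))
    ve(u / sqrt(sum(u^2)))
  })
  expect_gte(mods$variance_explained[1], max(rand_ve))
  # sign convention: mean correlation with module genes >= 0
  expect_gte(mean(cor(me, centered)), 0)
})

test_that("module-trait correlation matches the exact t-transform oracle", {
  d <- benchmark_expression(seed = 7, shift = c(2, 0, 0))
  tom <- tom_from_adjacency(adjacency_matrix(d$expr, 6))
  mods <- detect_modules(tom, d$expr, 80, 0.20)
  trait <- d$truth$trait
  mt <- module_trait_correlation(mods, trait)
  for (m in seq_len(ncol(mods$eigengenes))) {
    ct <- cor.test(mods$eigengenes[, m], trait)
    expect_equal(mt$correlation[m, 1], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(mt$p[m, 1], ct$p.value, tolerance = 1e-10)
  }
  # trait equal to an eigengene: correlation 1
  mt1 <- module_trait_correlation(mods, mods$eigengenes[, 1])
  expect_equal(mt1$correlation[1, 1], 1, tolerance = 1e-12)
  expect_lt(mt1$p[1, 1], 1e-12)
  expect_error(module_trait_correlation(mods, rep(1, nrow(mods$eigengenes))),
               class = "ichwmi_undefined_correlation_error")
})

test_that("MM and GS agree with closed-form correlation tests", {
  d <- benchmark_expression(seed = 7, shift = c(2, 0, 0))
  tom <- tom_from_adjacency(adjacency_matrix(d$expr, 6))
  mods <- detect_modules(tom, d$expr, 80, 0.20)
  trait <- d$truth$trait
  mt <- module_trait_correlation(mods, trait)
  best <- which.max(abs(mt$correlation[, 1]))
  st <- gene_mm_gs(d$expr, mods, best, trait)
  g <- st$gene_id[1]
  me <- mods$eigengenes[, best]
  expect_equal(st$mm[1], cor(d$expr$values[g, ], me), tolerance = 1e-12)
  expect_equal(st$gs[1],
               -log10(cor.test(d$expr$values[g, ], trait)$p.value),
               tolerance = 1e-10)
  expect_true(all(abs(st$mm) <= 1, na.rm = TRUE))
  expect_true(all(st$gs >= 0, na.rm = TRUE))
})

test_that("interesting-gene selection uses strict thresholds", {
  st <- structure(data.frame(gene_id = c("A", "B", "C"),
                             mm = c(0.95, 0.9, 0.91),
                             gs = c(1.2, 2.0, 0.85)),
                  class = c("gene_module_stats", "data.frame"))
  sel <- select_interesting(st, 0.9, 0.85)
  expect_equal(sel$members, "A") # B fails mm strictness, C fails gs strictness
})

test_that("trait-linked module genes are selected against the truth bundle", {
  d <- benchmark_expression(seed = 19, shift = c(2.5, 0, 0))
  tom <- tom_from_adjacency(adjacency_matrix(d$expr, 6))
  mods <- detect_modules(tom, d$expr, 80, 0.20)
  trait <- d$truth$trait
  mt <- module_trait_correlation(mods, trait)
  best <- which.max(abs(mt$correlation[, 1]))
  st <- gene_mm_gs(d$expr, mods, best, trait)
  sel <- select_interesting(st, 0.8, 1.3)
  truth_mod1 <- toupper(names(which(d$truth$module_labels == 1)))
  expect_gt(length(sel$members), 0)
  hits <- length(intersect(sel$members, truth_mod1))
  expect_gt(hits / length(sel$members), 0.9)       # selection is near-pure
  expect_gt(hits / length(truth_mod1), 0.5)        # and recovers the module
})
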