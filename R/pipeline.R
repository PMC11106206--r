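#' Pipeline configuration
#'
#' Collects every tunable of the two analysis arms in one validated list.
#' Defaults are the study settings: 30% variance prefilter, soft-threshold
#' candidates up to 20 with target R^2 0.85, min module size 80, merge cut
#' height 0.20, MM > 0.9 and GS > 0.85, |fold change| > 2 at BH FDR 0.05,
#' gate alpha 0.05 and 10,000 resamples. A single master seed fans out to
#' per-stage seeds by fixed offsets so stage reruns are independently
#' reproducible.
#'
#' @param filter_fraction Variance prefilter removal fraction.
#' @param beta_candidates Soft-threshold candidate powers.
#' @param r2_target Scale-free fit target.
#' @param min_module_size,merge_cut_height Module detection parameters.
#' @param mm_thr,gs_thr Interesting-gene thresholds.
#' @param fc_thr,fdr_thr DEG thresholds.
#' @param alpha Gatekeeping level.
#' @param n_resample Bootstrap/permutation resamples.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_fraction = 0.30,
                            beta_candidates = c(1:10, seq(12, 20, 2)),
                            r2_target = 0.85, min_module_size = 80,
                            merge_cut_height = 0.20, mm_thr = 0.9,
                            gs_thr = 0.85, fc_thr = 2, fdr_thr = 0.05,
                            alpha = 0.05, n_resample = 10000, seed = 1L) {
  cfg <- list(filter_fraction = filter_fraction,
              beta_candidates = beta_candidates, r2_target = r2_target,
              min_module_size = min_module_size,
              merge_cut_height = merge_cut_height, mm_thr = mm_thr,
              gs_thr = gs_thr, fc_thr = fc_thr, fdr_thr = fdr_thr,
              alpha = alpha, n_resample = n_resample, seed = as.integer(seed))
  assert_that(cfg$filter_fraction >= 0 && cfg$filter_fraction < 1,
              "filter_fraction must lie in [0, 1)")
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0,
              paste("unknown config keys:", paste(bad, collapse = ", ")))
  do.call(pipeline_config, raw)
}

config_digest <- function(cfg) {
  # stable short digest of the configuration for the report manifest
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

manifest <- function(cfg) {
  list(package = "ichwmi",
       version = as.character(utils::packageVersion("ichwmi")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = cfg$seed, config_digest = config_digest(cfg))
}

#' Run the gene-screening arm end-to-end
#'
#' Prefilter (pooled within-group variance at `filter_fraction`, with a
#' leave-one-out SVM evaluation of the kept genes) -> soft-threshold pick ->
#' TOM -> module detection -> module-trait correlation -> MM/GS of the most
#' trait-correlated module -> interesting-gene selection -> per-gene DEG
#' test with BH -> the candidate/finalist intersection funnel. Fully
#' deterministic given the configuration. When `out_dir` is given, all
#' intermediate tables and a JSON report are written.
#'
#' @param x An [expression_matrix()] with exactly the two comparison groups
#'   or more (the first two distinct labels are compared in the DEG stage
#'   unless `deg_groups` is given).
#' @param trait Numeric trait per sample (default: indicator of the first
#'   group).
#' @param degs_blood A [gene_set()] of externally derived DEGs for the
#'   second funnel operand (the study takes these pre-computed); default:
#'   the internal DEG set itself, which reduces the funnel to two stages.
#' @param cfg A [pipeline_config()].
#' @param deg_groups Length-2 character vector of labels for the DEG
#'   contrast.
#' @param out_dir Optional output directory.
#' @return A list of class `screen_report`.
#' @export
run_gene_screen <- function(x, trait = NULL, degs_blood = NULL,
                            cfg = pipeline_config(), deg_groups = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(x, "expr_matrix"), inherits(cfg, "pipeline_config"))
  groups <- unique(x$sample_groups)
  if (is.null(trait)) trait <- as.numeric(x$sample_groups == groups[1])
  if (is.null(deg_groups)) deg_groups <- groups[1:2]

  filt <- apply_filter(x, cfg$filter_fraction)
  xf <- subset_genes(x, filt$kept_gene_ids)
  loo <- loo_svm_eval(xf)
  st <- pick_soft_threshold(xf, cfg$beta_candidates, cfg$r2_target)
  tom <- tom_from_adjacency(adjacency_matrix(xf, st$chosen_power))
  mods <- detect_modules(tom, xf, cfg$min_module_size, cfg$merge_cut_height)
  n_mod <- ncol(mods$eigengenes)
  interesting <- gene_set(character(0), "interesting")
  mt <- NULL; stats <- NULL; best_module <- NA_integer_
  if (n_mod >= 1) {
    mt <- module_trait_correlation(mods, trait)
    best_module <- which.max(abs(mt$correlation[, 1]))
    stats <- gene_mm_gs(xf, mods, best_module, trait)
    interesting <- select_interesting(stats, cfg$mm_thr, cfg$gs_thr)
  }
  deg <- deg_test(x, deg_groups[1], deg_groups[2])
  degs_tissue <- filter_degs(deg, cfg$fc_thr, cfg$fdr_thr, label = "degs_tissue")
  if (is.null(degs_blood)) degs_blood <- gene_set(degs_tissue$members, "degs_blood")
  funnel <- screen_funnel(interesting, degs_tissue, degs_blood)

  report <- structure(list(
    filter = list(fraction = cfg$filter_fraction,
                  n_kept = length(filt$kept_gene_ids),
                  loo_accuracy = loo$accuracy, loo_f1 = loo$f1),
    soft_threshold = list(chosen_power = st$chosen_power,
                          fit_r2 = st$fit_r2[match(st$chosen_power,
                                                   st$candidate_powers)]),
    modules = list(n_modules = n_mod, sizes = mods$module_sizes,
                   best_module = best_module),
    module_trait = mt, gene_stats = stats, deg_table = deg,
    funnel = funnel, finalists = funnel$stages$finalists$members,
    manifest = manifest(cfg)),
    class = "screen_report")

  if (!is.null(out_dir)) write_screen_report(report, mods, out_dir)
  report
}

write_screen_report <- function(report, mods, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(data.frame(gene_id = names(mods$module_id), module = mods$module_id),
      "modules.tsv")
  if (ncol(mods$eigengenes) > 0)
    tsv(data.frame(sample = rownames(mods$eigengenes), mods$eigengenes),
        "eigengenes.tsv")
  if (!is.null(report$gene_stats)) tsv(report$gene_stats, "mm_gs.tsv")
  tsv(report$deg_table, "deg.tsv")
  json <- list(filter = report$filter, soft_threshold = report$soft_threshold,
               modules = list(n_modules = report$modules$n_modules,
                              best_module = report$modules$best_module),
               counts = as.list(report$funnel$counts),
               finalists = report$finalists, manifest = report$manifest)
  jsonlite::write_json(json, file.path(out_dir, "screen_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the DTI comparison arm end-to-end
#'
#' For each experimental arm: tensor fit -> FA map -> ROI mean FA -> paired
#' right/left ratios; the per-arm values are then assembled into the
#' groups x measures subgroup design (right/left/ratio for each structure)
#' and passed to [gatekeeping_compare()].
#'
#' @param dwis Named list (one entry per experimental arm) of
#'   [dwi_volume()]s.
#' @param rois A [roi_set()] shared by all arms.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory for the flattened ROI TSV and
#'   JSON report.
#' @return A list of class `dti_report`: `roi_stats` (per arm), `design`,
#'   `comparison` (a `gatekeeping_report`, or `NULL` with a warning for a
#'   single arm), `manifest`.
#' @export
run_dti_compare <- function(dwis, rois, cfg = pipeline_config(),
                            out_dir = NULL) {
  stopifnot(is.list(dwis), inherits(rois, "roi_set"),
            inherits(cfg, "pipeline_config"))
  arms <- names(dwis)
  assert_that(!is.null(arms) && all(nzchar(arms)), "dwis must be named by arm")
  roi_stats <- lapply(dwis, function(d) {
    fa <- compute_fa_map(d)
    st <- roi_mean_fa(fa, rois)
    st$ratio <- NA_real_
    rat <- fa_ratios(st)
    st$ratio[match(rat$name_right, st$name)] <- rat$ratio
    st
  })
  cells <- list()
  for (s in unique(rois$structure)) {
    for (side in c("right", "left")) {
      meas <- sprintf("FA_%s_%s", side, s)
      cells[[meas]] <- lapply(roi_stats, function(st)
        st$mean_fa[st$structure == s & st$side == side])
    }
    meas <- sprintf("FA_ratio_%s", s)
    cells[[meas]] <- lapply(roi_stats, function(st)
      st$ratio[st$structure == s & !is.na(st$ratio)])
  }
  design <- subgroup_design(cells)
  comparison <- NULL
  if (length(arms) >= 2) {
    comparison <- gatekeeping_compare(design, alpha = cfg$alpha,
                                      n_resample = cfg$n_resample,
                                      seed = cfg$seed)
  } else {
    warning("single arm supplied; omnibus comparison skipped")
  }
  report <- structure(list(roi_stats = roi_stats, design = design,
                           comparison = comparison, manifest = manifest(cfg)),
                      class = "dti_report")
  if (!is.null(out_dir)) write_dti_report(report, out_dir)
  report
}

write_dti_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- do.call(rbind, lapply(names(report$roi_stats), function(arm) {
    st <- report$roi_stats[[arm]]
    st$arm <- arm
    st
  }))
  write.table(flat, file.path(out_dir, "roi_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  json <- list(n_cells = report$design$n_cells,
               groups = report$design$groups,
               measures = report$design$measures,
               manifest = report$manifest)
  if (!is.null(report$comparison)) {
    json$comparisons <- lapply(report$comparison$measures, function(m) {
      out <- list(omnibus_p = m$omnibus$p, tested = m$tested,
                  bootstrap = lapply(m$bootstrap, function(ci)
                    list(mean = ci$point_estimate, ci_low = ci$ci_low,
                         ci_high = ci$ci_high)))
      if (!is.null(m$pairwise)) out$pairwise <- m$pairwise
      out
    })
  }
  jsonlite::write_json(json, file.path(out_dir, "dti_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
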