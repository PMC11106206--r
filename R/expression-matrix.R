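#' Expression matrix container
#'
#' Bundles a genes-by-samples matrix of (assumed log-scale) expression values
#' with unique gene identifiers and a categorical group label per sample.
#' This is the common currency of the screening arm: the variance prefilter,
#' the co-expression stage and the differential-expression test all consume
#' it.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. No
#'   missing values are allowed; impute before construction.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   colnames).
#' @param sample_groups Character or factor label per sample (e.g.
#'   `"perihematomal"`, `"white_matter"`, `"grey_matter"`).
#' @return An object of class `expr_matrix` with elements `values`,
#'   `gene_ids`, `sample_ids`, `sample_groups`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              sample_groups) {
  values <- as.matrix(values)
  assert_that(is.numeric(values), "expression values must be numeric")
  assert_that(!anyNA(values),
              "expression matrix contains missing values; impute first")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  sample_groups <- as.character(sample_groups)
  assert_that(length(gene_ids) == nrow(values), "gene_ids length mismatch")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(length(sample_ids) == ncol(values), "sample_ids length mismatch")
  assert_that(length(sample_groups) == ncol(values),
              "one group label per sample required")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         sample_groups = sample_groups),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples; groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s(%d)", names(table(x$sample_groups)),
                            table(x$sample_groups)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Subset an expr_matrix by gene identifiers, preserving order of `genes`.
subset_genes <- function(x, genes) {
  assert_that(all(genes %in% x$gene_ids), "unknown gene identifiers")
  expression_matrix(x$values[genes, , drop = FALSE], genes, x$sample_ids,
                    x$sample_groups)
}

#' Write / read the expression TSV dialect
#'
#' The on-disk dialect is a (optionally gzipped) TSV with gene identifiers
#' in the first column (`gene_id`) and one column per sample, plus a
#' separate sample-annotation TSV with columns `sample`, `group` and
#' optionally `trait`.
#'
#' @param x An `expr_matrix`.
#' @param expr_path Path for the expression TSV (use a `.gz` suffix for
#'   gzip compression).
#' @param ann_path Path for the sample-annotation TSV.
#' @param trait Optional numeric trait per sample written to the annotation.
#' @return `write_expression` returns the paths invisibly;
#'   `read_expression` returns an `expr_matrix` (with a `trait` attribute
#'   when the annotation has a trait column).
#' @export
write_expression <- function(x, expr_path, ann_path, trait = NULL) {
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
  con <- if (grepl("\\.gz$", expr_path)) gzfile(expr_path, "w") else file(expr_path, "w")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ann <- data.frame(sample = x$sample_ids, group = x$sample_groups)
  if (!is.null(trait)) ann$trait <- trait
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr = expr_path, ann = ann_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(expr_path, ann_path) {
  df <- read.delim(expr_path, check.names = FALSE)
  assert_that(colnames(df)[1] == "gene_id",
              "expression TSV must start with a gene_id column")
  ann <- read.delim(ann_path, check.names = FALSE)
  assert_that(all(c("sample", "group") %in% colnames(ann)),
              "annotation TSV needs 'sample' and 'group' columns")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  idx <- match(colnames(vals), ann$sample)
  assert_that(!anyNA(idx), "annotation is missing samples from the matrix")
  out <- expression_matrix(vals, df$gene_id, colnames(vals), ann$group[idx])
  if ("trait" %in% colnames(ann)) attr(out, "trait") <- ann$trait[idx]
  out
}
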