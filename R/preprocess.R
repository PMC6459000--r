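#' Normalise each sample to one million reads
#'
#' Rescales every sample (column) of a linear-stage expression matrix so its
#' total is 1e6, leaving within-sample gene proportions unchanged.
#'
#' @param x linear genes x samples matrix.
#' @return matrix with all column sums equal to 1e6.
#' @export
normalize_library_size <- function(x) {
  check_expr_matrix(x)
  assert_stage(x, "linear", "normalize_library_size()")
  tot <- colSums(x)
  if (any(tot <= 0)) {
    stop("sample(s) with non-positive total counts: ",
         paste(colnames(x)[tot <= 0], collapse = ", "))
  }
  set_stage(sweep(x, 2, 1e6 / tot, `*`), "linear")
}

#' Remove low-abundance genes
#'
#' A gene is removed iff its value is below `threshold` in at least
#' `sample_fraction` of the samples (strict `<` on the value, `>=` on the
#' fraction). Applied on the linear RPKM scale, before the log transform.
#'
#' @param x linear genes x samples matrix.
#' @param threshold abundance threshold (RPKM units).
#' @param sample_fraction fraction of samples that must be below threshold
#'   for removal.
#' @return matrix with failing genes dropped; gene order preserved.
#' @export
filter_low_abundance <- function(x, threshold = 0.1, sample_fraction = 0.8) {
  check_expr_matrix(x)
  assert_stage(x, "linear", "filter_low_abundance()")
  frac_below <- rowMeans(x < threshold)
  keep <- frac_below < sample_fraction
  set_stage(x[keep, , drop = FALSE], "linear")
}

#' Pseudocount-and-log transform
#'
#' Maps every value v to log2(v + 1) and flips the stage flag to post-log.
#'
#' @param x linear genes x samples matrix (nonnegative).
#' @return post-log matrix.
#' @export
log_transform <- function(x) {
  check_expr_matrix(x)
  assert_stage(x, "linear", "log_transform()")
  if (any(x < 0)) stop("negative values cannot be log-transformed")
  set_stage(log2(x + 1), "log2")
}

#' Drop samples failing RNA-quality gates
#'
#' Retains exactly the samples with RIN >= `min_rin` (inclusive boundary)
#' and a TRUE usable flag.
#'
#' @param x genes x samples matrix (either stage).
#' @param meta sample metadata covering every column of `x` (columns
#'   `sample`, `rin`, `usable`).
#' @param min_rin minimum RNA integrity number.
#' @return list with the filtered `expr` and `meta`.
#' @export
filter_samples_by_quality <- function(x, meta, min_rin = 6) {
  check_expr_matrix(x)
  missing <- setdiff(colnames(x), meta$sample)
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(x), meta$sample), , drop = FALSE]
  keep <- meta$rin >= min_rin & meta$usable
  out <- x[, keep, drop = FALSE]
  attr(out, "stage") <- expr_stage(x)
  list(expr = out, meta = meta[keep, , drop = FALSE])
}

#' Partition a cohort by tissue, gender and age bin
#'
#' Splits the retained samples into a named list of sub-matrices keyed
#' `"tissue|gender|age_bin"`. Tissues derived from cultured cell lines
#' (labels starting with `"Cells"`) are excluded.
#'
#' @param x genes x samples matrix (post quality gate).
#' @param meta matching metadata.
#' @param age_bins ordered vector of valid age-bin labels.
#' @param exclude_cell_lines drop cell-line-derived tissues.
#' @return named list of genes x samples matrices; exhaustive and disjoint
#'   over retained samples.
#' @export
partition_cohort <- function(x, meta,
                             age_bins = c("20-29", "30-39", "40-49",
                                          "50-59", "60-69", "70-79"),
                             exclude_cell_lines = TRUE) {
  check_expr_matrix(x)
  meta <- meta[match(colnames(x), meta$sample), , drop = FALSE]
  bad <- setdiff(unique(meta$age_bin), age_bins)
  if (length(bad)) {
    stop("unknown age bin label(s): ", paste(bad, collapse = ", "))
  }
  if (exclude_cell_lines) {
    keep <- !startsWith(meta$tissue, "Cells")
    x <- x[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (nrow(meta) == 0L) return(structure(list(), names = character(0)))
  key <- paste(meta$tissue, meta$gender, meta$age_bin, sep = "|")
  idx <- split(seq_len(ncol(x)), key)
  stage <- expr_stage(x)
  lapply(idx, function(i) set_stage(x[, i, drop = FALSE], stage))
}

#' Run the full cohort preprocessing chain
#'
#' Fixed order: library-size normalisation, low-abundance filter (both on
#' the linear RPKM scale), pseudocount + log2 transform, RNA-quality gate,
#' partition by tissue/gender/age bin.
#'
#' @param expr linear genes x samples matrix.
#' @param meta sample metadata (`sample`, `tissue`, `gender`, `age_bin`,
#'   `rin`, `usable`).
#' @param threshold,sample_fraction abundance-filter parameters.
#' @param min_rin quality gate.
#' @param age_bins valid age-bin labels.
#' @param exclude_cell_lines drop cell-line tissues during partitioning.
#' @return list with `expr` (post-log, quality-gated), `meta` (retained
#'   samples) and `partition` (the named sub-matrix list).
#' @export
preprocess_cohort <- function(expr, meta, threshold = 0.1,
                              sample_fraction = 0.8, min_rin = 6,
                              age_bins = c("20-29", "30-39", "40-49",
                                           "50-59", "60-69", "70-79"),
                              exclude_cell_lines = TRUE) {
  x <- normalize_library_size(expr)
  x <- filter_low_abundance(x, threshold, sample_fraction)
  x <- log_transform(x)
  gated <- filter_samples_by_quality(x, meta, min_rin)
  part <- partition_cohort(gated$expr, gated$meta, age_bins,
                           exclude_cell_lines)
  list(expr = gated$expr, meta = gated$meta, partition = part)
}
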