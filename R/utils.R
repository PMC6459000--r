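#' geroscreen: transcriptomic age classifiers and geroprotector screening
#'
#' Tools to (i) simulate age-stratified expression cohorts, drug perturbation
#' tables and worm lifespan-machine output; (ii) preprocess cohorts the way
#' large tissue atlases are prepared (library-size normalisation, abundance
#' filtering, log transform, RNA-quality gating, partitioning); (iii) train
#' and gate random-forest young-vs-old age classifiers; (iv) score drug
#' perturbations by applying fold changes to a prototypical "middle age"
#' transcriptome and classifying the result; (v) rank drugs by cross-model
#' hypergeometric enrichment with FDR control; and (vi) analyse worm survival
#' and population-activity validation data.
#'
#' @keywords internal
"_PACKAGE"

# Derive a per-stage seed from a global seed; stays inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * as.double(k)) %% 2147483647L) + 1L
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' @param scores numeric vector of predicted scores (higher = more positive).
#' @param labels logical or 0/1 vector; `TRUE` marks the positive class.
#' @return AUC in \[0, 1\]; ties handled by midranks.
#' @keywords internal
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC-AUC undefined: need both classes present")
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Sensitivity / specificity / accuracy at the 0.5 probability threshold;
# "young" is the positive class throughout the package.
threshold_metrics <- function(prob_young, is_young, threshold = 0.5) {
  pred_young <- prob_young > threshold
  tp <- sum(pred_young & is_young)
  tn <- sum(!pred_young & !is_young)
  fp <- sum(pred_young & !is_young)
  fn <- sum(!pred_young & is_young)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(prob_young)
  )
}

# Stage bookkeeping for expression matrices: "linear" (RPKM-like) before the
# pseudocount+log step, "log2" after.
expr_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) "linear" else s
}

set_stage <- function(x, stage) {
  attr(x, "stage") <- match.arg(stage, c("linear", "log2"))
  x
}

assert_stage <- function(x, stage, what) {
  if (!identical(expr_stage(x), stage)) {
    stop(sprintf("%s expects a matrix on the %s stage (got '%s')",
                 what, stage, expr_stage(x)), call. = FALSE)
  }
  invisible(x)
}

check_expr_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix (genes x samples)", what),
         call. = FALSE)
  }
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop(sprintf("%s is empty", what), call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop(sprintf("%s needs unique gene ids as rownames", what), call. = FALSE)
  }
  if (is.null(colnames(x))) {
    stop(sprintf("%s needs sample ids as colnames", what), call. = FALSE)
  }
  invisible(x)
}
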