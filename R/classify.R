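#' Per-gene equal-variance two-sample t-test filter
#'
#' Vectorised pooled-variance (equal-variance) two-sided t-test per gene,
#' the classical row-wise differential filter. Genes with zero pooled
#' variance and equal means get p = 1 (no signal); zero pooled variance
#' with unequal means gives p = 0.
#'
#' @param young,old genes x samples matrices sharing rownames.
#' @param alpha significance level; genes with p < alpha survive.
#' @return data.frame (`gene`, `p`) for the surviving genes, in input order.
#' @export
differential_filter <- function(young, old, alpha = 0.01) {
  if (!identical(rownames(young), rownames(old))) {
    stop("young and old matrices must share the same genes")
  }
  n1 <- ncol(young); n2 <- ncol(old)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(young); m2 <- rowMeans(old)
  v1 <- rowSums((young - m1)^2) / (n1 - 1)
  v2 <- rowSums((old - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2),
              ifelse(m1 == m2, 1, 0))
  keep <- p < alpha
  data.frame(gene = rownames(young)[keep], p = p[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble one binary young-vs-old comparison dataset
#'
#' From a tissue/gender partition, builds the training unit for one age
#' classifier: both sides must have at least `min_n` samples (otherwise a
#' skip signal, `NULL`, is returned rather than an error); genes are
#' restricted to the perturbation universe, pruned of the `abundance_drop`
#' fraction with the lowest mean expression over the combined comparison
#' samples, and then of genes failing the differential filter at
#' `de_alpha`.
#'
#' @param partition named list from [partition_cohort()].
#' @param tissue,gender,young_bin comparison coordinates.
#' @param old_bin the old age bin (fixed at "60-69" in the standard design).
#' @param universe gene ids present in the perturbation data.
#' @param min_n minimum samples per side.
#' @param abundance_drop fraction of lowest-mean genes to drop.
#' @param de_alpha differential-filter level (no multiplicity correction).
#' @return an `age_dataset` object, or `NULL` (skip) when a side is too
#'   small or no gene survives.
#' @export
assemble_comparison <- function(partition, tissue, gender, young_bin,
                                old_bin = "60-69", universe,
                                min_n = 10, abundance_drop = 0.10,
                                de_alpha = 0.01) {
  if (identical(young_bin, old_bin)) {
    stop("young_bin and old_bin must differ")
  }
  young <- partition[[paste(tissue, gender, young_bin, sep = "|")]]
  old <- partition[[paste(tissue, gender, old_bin, sep = "|")]]
  if (is.null(young) || is.null(old) ||
      ncol(young) < min_n || ncol(old) < min_n) {
    return(NULL)
  }
  genes <- intersect(rownames(young), universe)
  if (length(genes) == 0L) return(NULL)
  young <- young[genes, , drop = FALSE]
  old <- old[genes, , drop = FALSE]

  n_drop <- floor(abundance_drop * length(genes))
  if (n_drop > 0) {
    mean_expr <- rowMeans(cbind(young, old))
    keep <- rank(mean_expr, ties.method = "first") > n_drop
    young <- young[keep, , drop = FALSE]
    old <- old[keep, , drop = FALSE]
  }

  de <- differential_filter(young, old, de_alpha)
  if (nrow(de) == 0L) return(NULL)
  structure(list(
    tissue = tissue, gender = gender,
    young_bin = young_bin, old_bin = old_bin,
    genes = de$gene, de_p = stats::setNames(de$p, de$gene),
    young = set_stage(young[de$gene, , drop = FALSE], "log2"),
    old = set_stage(old[de$gene, , drop = FALSE], "log2")
  ), class = "age_dataset")
}

#' @export
print.age_dataset <- function(x, ...) {
  cat(sprintf("age comparison: %s / %s, young %s (n=%d) vs old %s (n=%d), %d genes\n",
              x$tissue, x$gender, x$young_bin, ncol(x$young),
              x$old_bin, ncol(x$old), length(x$genes)))
  invisible(x)
}

default_mtry_grid <- function(p) {
  s <- floor(sqrt(p))
  sort(unique(pmin(pmax(c(floor(s / 2), s, 2 * s, floor(p / 3)), 1L), p)))
}

# stratified fold ids: within each class, shuffle a balanced 1..k assignment
stratified_folds <- function(is_young, k) {
  fold <- integer(length(is_young))
  for (cls in c(TRUE, FALSE)) {
    i <- which(is_young == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Fit a random-forest transcriptomic age classifier
#'
#' Implements the standard recipe for binary young-vs-old classification
#' from expression data: the majority class is randomly downsampled to the
#' minority size; a stratified 70/30 train/test split is made; per-gene
#' center/scale constants are estimated on the training split only; the
#' forest (500 trees) is tuned over an mtry grid by repeated stratified
#' 10-fold cross-validation maximising ROC-AUC (ties go to the smallest
#' mtry); cross-validated sensitivity and specificity at the 0.5
#' probability threshold are recorded; the winning mtry is refit on the
#' full training split and evaluated on the held-out 30%.
#'
#' "Young" is the positive class for all probabilities and metrics.
#'
#' @param dataset an `age_dataset` from [assemble_comparison()].
#' @param train_fraction fraction of balanced samples used for training.
#' @param cv_folds,cv_repeats cross-validation design.
#' @param n_trees trees per forest.
#' @param mtry_grid candidate values for variables tried per split;
#'   default `{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p)), floor(p/3)}`
#'   clipped to `[1, p]`.
#' @param de_alpha optional within-training feature reduction: when
#'   non-NULL, the per-gene differential filter is re-run on the training
#'   split only and the model keeps the genes with p < `de_alpha`. Doing
#'   the selection inside the split keeps the held-out metrics (and hence
#'   the quality gate) honest; selection on the full comparison leaks into
#'   them. If no gene survives, the single smallest-p gene is kept.
#' @param seed integer seed controlling balancing, splitting, folds and the
#'   forests; identical inputs and seed give identical models.
#' @return an object of class `age_classifier` carrying the fitted forest,
#'   the gene list with center/scale constants, CV and test metrics, and
#'   the dataset provenance.
#' @export
age_classifier <- function(dataset, train_fraction = 0.70, cv_folds = 10,
                           cv_repeats = 3, n_trees = 500, mtry_grid = NULL,
                           de_alpha = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "age_dataset"))
  x <- t(cbind(dataset$young, dataset$old))       # samples x genes
  is_young <- rep(c(TRUE, FALSE), c(ncol(dataset$young), ncol(dataset$old)))
  if (!any(is_young) || all(is_young)) stop("both classes must be nonempty")

  set.seed(derive_seed(seed, 11L))
  # class balancing: downsample the majority class
  n_min <- min(sum(is_young), sum(!is_young))
  keep <- c(sample(which(is_young), n_min), sample(which(!is_young), n_min))
  x <- x[keep, , drop = FALSE]
  is_young <- is_young[keep]

  # stratified 70/30 split
  set.seed(derive_seed(seed, 12L))
  n_train_cls <- floor(train_fraction * n_min)
  train_idx <- c(sample(which(is_young), n_train_cls),
                 sample(which(!is_young), n_train_cls))
  test_idx <- setdiff(seq_along(is_young), train_idx)
  if (n_train_cls < cv_folds) {
    stop(sprintf(paste0("only %d training samples per class but %d CV ",
                        "folds requested; lower cv_folds"),
                 n_train_cls, cv_folds))
  }

  xtr <- x[train_idx, , drop = FALSE]
  ytr <- is_young[train_idx]

  # optional feature reduction inside the training split
  if (!is.null(de_alpha)) {
    de <- differential_filter(t(xtr[ytr, , drop = FALSE]),
                              t(xtr[!ytr, , drop = FALSE]), alpha = Inf)
    sel <- de$gene[de$p < de_alpha]
    if (length(sel) == 0L) sel <- de$gene[which.min(de$p)]
    x <- x[, sel, drop = FALSE]
    xtr <- xtr[, sel, drop = FALSE]
  }

  # center/scale constants from the training split only
  center <- colMeans(xtr)
  scale <- apply(xtr, 2, stats::sd)
  scale[scale == 0] <- 1
  xtr_s <- scale(xtr, center = center, scale = scale)
  colnames(xtr_s) <- colnames(x)

  p <- ncol(xtr_s)
  if (is.null(mtry_grid)) mtry_grid <- default_mtry_grid(p)
  mtry_grid <- sort(unique(pmin(pmax(as.integer(mtry_grid), 1L), p)))
  yf <- factor(ifelse(ytr, "young", "old"), levels = c("young", "old"))

  # repeated stratified k-fold CV, ROC-AUC per repeat averaged
  cv_tab <- data.frame(mtry = mtry_grid, roc_auc = NA_real_,
                       sensitivity = NA_real_, specificity = NA_real_)
  for (gi in seq_along(mtry_grid)) {
    auc_rep <- numeric(cv_repeats)
    prob_all <- numeric(0); truth_all <- logical(0)
    for (r in seq_len(cv_repeats)) {
      set.seed(derive_seed(seed, 100L + r))   # same folds for every mtry
      fold <- stratified_folds(ytr, cv_folds)
      prob <- numeric(length(ytr))
      for (f in seq_len(cv_folds)) {
        hold <- fold == f
        fit <- ranger::ranger(
          x = xtr_s[!hold, , drop = FALSE], y = yf[!hold],
          num.trees = n_trees, mtry = mtry_grid[gi], probability = TRUE,
          num.threads = 1,
          seed = derive_seed(seed, 1000L + 37L * r + f + 13L * gi)
        )
        prob[hold] <- predict(fit, data = xtr_s[hold, , drop = FALSE],
                              num.threads = 1)$predictions[, "young"]
      }
      auc_rep[r] <- roc_auc(prob, ytr)
      prob_all <- c(prob_all, prob)
      truth_all <- c(truth_all, ytr)
    }
    thr <- threshold_metrics(prob_all, truth_all)
    cv_tab$roc_auc[gi] <- mean(auc_rep)
    cv_tab$sensitivity[gi] <- thr$sensitivity
    cv_tab$specificity[gi] <- thr$specificity
  }
  best <- which(cv_tab$roc_auc == max(cv_tab$roc_auc))[1L]  # smallest mtry wins ties

  final <- ranger::ranger(
    x = xtr_s, y = yf, num.trees = n_trees, mtry = mtry_grid[best],
    probability = TRUE, num.threads = 1, seed = derive_seed(seed, 21L)
  )

  model <- structure(list(
    tissue = dataset$tissue, gender = dataset$gender,
    young_bin = dataset$young_bin, old_bin = dataset$old_bin,
    genes = colnames(x), center = center, scale = scale,
    forest = final, mtry = mtry_grid[best], n_trees = n_trees,
    cv = list(roc_auc = cv_tab$roc_auc[best],
              sensitivity = cv_tab$sensitivity[best],
              specificity = cv_tab$specificity[best],
              grid = cv_tab, folds = cv_folds, repeats = cv_repeats),
    test = NULL, seed = seed, n_per_class = n_min,
    n_train = length(train_idx), n_test = length(test_idx),
    train_samples = rownames(x)[train_idx],
    test_samples = rownames(x)[test_idx]
  ), class = "age_classifier")

  model$test <- evaluate_classifier(model,
                                    t(x[test_idx, , drop = FALSE]),
                                    is_young[test_idx])
  model
}

#' Predict probability-young for new transcriptomes
#'
#' Applies the model's stored center/scale constants and returns the
#' forest's probability of the "young" class.
#'
#' @param object an `age_classifier`.
#' @param newdata genes x samples numeric matrix (post-log scale) covering
#'   the model's genes, or a named vector for a single sample.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\], one per sample.
#' @export
predict.age_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample"))
  }
  miss <- setdiff(object$genes, rownames(newdata))
  if (length(miss)) {
    stop("newdata is missing model genes: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  }
  xs <- scale(t(newdata[object$genes, , drop = FALSE]),
              center = object$center, scale = object$scale)
  colnames(xs) <- object$genes
  stats::setNames(
    predict(object$forest, data = xs,
            num.threads = 1)$predictions[, "young"],
    colnames(newdata)
  )
}

#' Evaluate a classifier on held-out samples
#'
#' @param model an `age_classifier`.
#' @param newdata genes x samples matrix of held-out transcriptomes
#'   (disjoint from training).
#' @param is_young logical vector: TRUE for young samples.
#' @return list with `roc_auc` and `accuracy` (at the 0.5 probability cut).
#' @export
evaluate_classifier <- function(model, newdata, is_young) {
  if (all(is_young) || !any(is_young)) {
    stop("held-out set has a single class; ROC-AUC undefined")
  }
  prob <- predict(model, newdata)
  list(roc_auc = roc_auc(prob, is_young),
       accuracy = threshold_metrics(prob, is_young)$accuracy)
}

#' Model quality gate
#'
#' A model passes iff all five gated metrics strictly exceed the cutoff:
#' training (cross-validated) ROC-AUC, sensitivity and specificity, and
#' test ROC-AUC and accuracy.
#'
#' @param model an `age_classifier`.
#' @param cutoff gate value, default 0.75.
#' @return logical scalar.
#' @export
passes_gate <- function(model, cutoff = 0.75) {
  m <- gated_metrics(model)
  all(!is.na(m)) && all(m > cutoff)
}

gated_metrics <- function(model) {
  c(cv_roc_auc = model$cv$roc_auc,
    cv_sensitivity = model$cv$sensitivity,
    cv_specificity = model$cv$specificity,
    test_roc_auc = model$test$roc_auc,
    test_accuracy = model$test$accuracy)
}

#' Select the models passing the quality gate
#'
#' @param models list of `age_classifier` objects.
#' @param cutoff gate value applied to all five metrics (strict >).
#' @return the sub-list of passing models.
#' @export
select_models <- function(models, cutoff = 0.75) {
  Filter(function(m) passes_gate(m, cutoff), models)
}

#' Tabulate models and their gated metrics
#'
#' @param models list of `age_classifier` objects.
#' @param cutoff gate value.
#' @return data.frame: provenance, five gated metrics, pass flag.
#' @export
models_report <- function(models, cutoff = 0.75) {
  if (length(models) == 0L) {
    return(data.frame(tissue = character(0), gender = character(0),
                      young_bin = character(0), cv_roc_auc = numeric(0),
                      cv_sensitivity = numeric(0), cv_specificity = numeric(0),
                      test_roc_auc = numeric(0), test_accuracy = numeric(0),
                      pass = logical(0)))
  }
  do.call(rbind, lapply(models, function(m) {
    g <- gated_metrics(m)
    data.frame(tissue = m$tissue, gender = m$gender, young_bin = m$young_bin,
               cv_roc_auc = g[["cv_roc_auc"]],
               cv_sensitivity = g[["cv_sensitivity"]],
               cv_specificity = g[["cv_specificity"]],
               test_roc_auc = g[["test_roc_auc"]],
               test_accuracy = g[["test_accuracy"]],
               pass = passes_gate(m, cutoff),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.age_classifier <- function(x, ...) {
  cat(sprintf("age classifier: %s / %s, young %s vs old %s\n",
              x$tissue, x$gender, x$young_bin, x$old_bin))
  cat(sprintf("  %d genes, %d trees, mtry %d, %d samples/class\n",
              length(x$genes), x$n_trees, x$mtry, x$n_per_class))
  g <- gated_metrics(x)
  cat(sprintf("  CV ROC-AUC %.3f, sens %.3f, spec %.3f | test ROC-AUC %.3f, acc %.3f\n",
              g[1], g[2], g[3], g[4], g[5]))
  cat(sprintf("  quality gate (>0.75): %s\n",
              if (passes_gate(x)) "PASS" else "fail"))
  invisible(x)
}

#' @export
summary.age_classifier <- function(object, ...) {
  print(object)
  cat("\nCV tuning grid:\n")
  print(object$cv$grid, row.names = FALSE)
  invisible(object)
}
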