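#' Build a model's prototypical "middle age" transcriptome
#'
#' Per gene, the average of the median expression over the young samples
#' and the median over the old samples, on the post-log scale. This is the
#' baseline profile to which drug fold changes are applied; by
#' construction a model should classify it near probability 0.5.
#'
#' @param dataset the `age_dataset` the model was trained on.
#' @param genes gene ids to report (default: the dataset's genes); every
#'   requested gene must be present.
#' @return named numeric vector (post-log values >= 0).
#' @export
middle_age_profile <- function(dataset, genes = dataset$genes) {
  stopifnot(inherits(dataset, "age_dataset"))
  miss <- setdiff(genes, rownames(dataset$young))
  if (length(miss)) {
    stop("gene(s) missing from dataset: ", paste(miss, collapse = ", "))
  }
  y <- apply(dataset$young[genes, , drop = FALSE], 1, stats::median)
  o <- apply(dataset$old[genes, , drop = FALSE], 1, stats::median)
  (y + o) / 2
}

#' Collapse probe-level fold changes to gene level
#'
#' Each gene's fold change is the median of its probes' fold changes
#' (even-count medians use the midpoint convention); genes with no probe
#' are absent from the output.
#'
#' @param folds named numeric vector (probe -> fold change) or an
#'   instances x probes matrix with probe ids as colnames.
#' @param probe_map data.frame with columns `probe`, `gene`; each probe
#'   maps to at most one gene.
#' @return gene-level vector or instances x genes matrix.
#' @export
collapse_probes <- function(folds, probe_map) {
  if (is.null(probe_map) || nrow(probe_map) == 0L) {
    stop("probe map is empty")
  }
  if (anyDuplicated(probe_map$probe)) {
    stop("a probe maps to more than one gene")
  }
  if (is.matrix(folds)) {
    probes <- intersect(colnames(folds), probe_map$probe)
    gene_of <- probe_map$gene[match(probes, probe_map$probe)]
    genes <- unique(gene_of)
    out <- vapply(genes, function(g) {
      apply(folds[, probes[gene_of == g], drop = FALSE], 1, stats::median)
    }, numeric(nrow(folds)))
    if (nrow(folds) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(rownames(folds), genes))
    out
  } else {
    probes <- intersect(names(folds), probe_map$probe)
    gene_of <- probe_map$gene[match(probes, probe_map$probe)]
    vapply(split(folds[probes], gene_of), stats::median, numeric(1))
  }
}

#' Apply linear fold changes to a post-log profile
#'
#' For each gene with post-log value v and linear fold f: linearise
#' x = 2^v - 1, apply x' = max(f * x, 0), return v' = log2(x' + 1). A fold
#' of 1 is the identity and v = 0 is a fixed point. Genes missing from
#' `folds` default to 1 with a warning.
#'
#' @param profile named post-log vector (e.g. from [middle_age_profile()]).
#' @param folds named linear-scale fold-change vector; all values must be
#'   positive.
#' @param drug label used in error messages.
#' @return named post-log vector, same genes and order as `profile`.
#' @export
apply_fold_changes <- function(profile, folds, drug = "perturbation") {
  f <- folds[names(profile)]
  missing <- is.na(f)
  if (any(missing)) {
    warning(sprintf("%s: %d gene(s) missing fold changes; defaulting to 1",
                    drug, sum(missing)))
    f[missing] <- 1
  }
  bad <- which(f <= 0)
  if (length(bad)) {
    stop(sprintf("%s: non-positive fold change for gene %s",
                 drug, names(profile)[bad[1L]]))
  }
  x <- 2^profile - 1
  log2(pmax(as.numeric(f) * x, 0) + 1)
}

#' Classify drug-induced transcriptomes under every model
#'
#' For each model, applies each perturbation instance's fold changes to the
#' model's middle-age profile and returns the model's probability-young of
#' the induced transcriptome (the model's stored center/scale constants are
#' applied before prediction). An instance missing fold changes for more
#' than half of a model's genes gets an NA cell, excluded downstream.
#'
#' @param models named list of `age_classifier` objects.
#' @param profiles named list of middle-age profiles, keyed like `models`.
#' @param pert a `perturbation_table`.
#' @return instances x models matrix of probabilities (NA = flagged
#'   missing).
#' @export
classify_perturbations <- function(models, profiles, pert) {
  stopifnot(inherits(pert, "perturbation_table"))
  if (!identical(names(models), names(profiles))) {
    stop("models and profiles must be parallel named lists")
  }
  n_inst <- nrow(pert$folds)
  out <- matrix(NA_real_, n_inst, length(models),
                dimnames = list(pert$meta$instance, names(models)))
  for (mk in names(models)) {
    model <- models[[mk]]
    profile <- profiles[[mk]]
    genes <- model$genes
    if (!identical(sort(names(profile)), sort(genes))) {
      stop("profile genes must match the model's gene list: ", mk)
    }
    covered <- intersect(genes, colnames(pert$folds))
    if (length(covered) < length(genes)) {
      if (length(covered) <= length(genes) / 2) next   # all cells stay NA
      warning(sprintf("%s: %d model gene(s) without fold changes default to 1",
                      mk, length(genes) - length(covered)))
    }
    f <- matrix(1, n_inst, length(genes),
                dimnames = list(pert$meta$instance, genes))
    f[, covered] <- pert$folds[, covered, drop = FALSE]
    if (any(f <= 0)) {
      bad <- which(f <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-positive fold change (instance %s, gene %s)",
                   rownames(f)[bad[1L]], colnames(f)[bad[2L]]))
    }
    x_mid <- 2^profile[genes] - 1
    induced <- log2(pmax(sweep(f, 2, x_mid, `*`), 0) + 1)  # instances x genes
    out[, mk] <- predict(model, t(induced))
  }
  out
}

#' Consolidate instance-level probabilities to one score per drug
#'
#' Per (drug, model) cell, the maximum probability-young over the drug's
#' instances -- the most geroprotective prediction -- ignoring NA cells.
#' A drug with all instances missing for a model keeps an NA cell.
#'
#' @param prob instances x models probability matrix.
#' @param instance_drug character vector mapping each instance (row) to its
#'   drug.
#' @return drugs x models probability matrix.
#' @export
consolidate_per_drug <- function(prob, instance_drug) {
  if (length(instance_drug) != nrow(prob)) {
    stop("instance_drug must have one entry per probability row")
  }
  drugs <- unique(instance_drug)
  out <- matrix(NA_real_, length(drugs), ncol(prob),
                dimnames = list(drugs, colnames(prob)))
  for (d in drugs) {
    sub <- prob[instance_drug == d, , drop = FALSE]
    out[d, ] <- apply(sub, 2, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  }
  out
}

#' Convert probabilities to the geroprotective index
#'
#' Centers each model's probabilities at 0 (p - 0.5) and, in the default
#' `"rescaled"` mode, rescales each model column by a single positive
#' factor so the column's maximum absolute index is 0.5 (for comparability
#' across models); `"plain"` keeps p - 0.5 unscaled. Order within a column
#' is preserved and a positive index always means p > 0.5.
#'
#' @param prob drugs x models probability matrix (values in \[0, 1\]).
#' @param mode `"rescaled"` (default) or `"plain"`.
#' @return drugs x models index matrix with values in \[-0.5, 0.5\].
#' @export
geroprotective_index <- function(prob, mode = c("rescaled", "plain")) {
  mode <- match.arg(mode)
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  centered <- prob - 0.5
  if (mode == "plain") return(centered)
  m <- suppressWarnings(apply(abs(centered), 2, max, na.rm = TRUE))
  fac <- ifelse(is.finite(m) & m > 0, 0.5 / m, 0)
  sweep(centered, 2, fac, `*`)
}
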