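#' Run the full in silico geroprotector screen
#'
#' End-to-end pipeline on a cohort and a perturbation table: preprocess
#' (normalise, abundance-filter, log, quality-gate, partition), assemble
#' every available young-vs-old comparison, train and gate age
#' classifiers, build middle-age profiles, classify drug-induced
#' transcriptomes, consolidate to one score per drug and model, convert
#' to the geroprotective index, derive the MAD cutoff, and rank drugs by
#' hypergeometric enrichment with FDR control.
#'
#' @param expr linear genes x samples expression matrix.
#' @param meta sample metadata (`sample`, `tissue`, `gender`, `age_bin`,
#'   `rin`, `usable`).
#' @param pert a `perturbation_table`.
#' @param old_bin the old age bin.
#' @param young_bins candidate young bins (every tissue/gender/young-bin
#'   combination with enough samples yields one model).
#' @param min_n minimum samples per comparison side.
#' @param abundance_drop fraction of least-abundant genes dropped per
#'   comparison.
#' @param de_alpha differential-filter level.
#' @param de_scope where the differential filter runs: `"train"` (default)
#'   applies it inside each model's 70% training split so that held-out
#'   metrics and the quality gate stay free of selection leakage;
#'   `"comparison"` applies it to the full young-vs-old comparison before
#'   splitting (the literal methods-text order).
#' @param train_fraction,cv_folds,cv_repeats,n_trees,mtry_grid classifier
#'   recipe (see [age_classifier()]).
#' @param gate_cutoff quality-gate value applied to all five metrics.
#' @param index_mode `"rescaled"` or `"plain"` (see
#'   [geroprotective_index()]).
#' @param alpha candidate-list threshold on q.
#' @param fdr_method `"BH"` or `"BY"`.
#' @param min_rin RNA-quality gate.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param verbose print progress.
#' @return object of class `gero_screen`: trained `models`, gated
#'   `passing` model names, `index` matrix, `cutoff`, `ranking`
#'   data.frame, `candidates`, `status` (`"ok"` or
#'   `"no_passing_models"`), stage `counts`, and the call parameters.
#' @export
gero_screen <- function(expr, meta, pert,
                        old_bin = "60-69",
                        young_bins = c("20-29", "30-39", "40-49", "50-59"),
                        min_n = 10, abundance_drop = 0.10, de_alpha = 0.01,
                        de_scope = c("train", "comparison"),
                        train_fraction = 0.70, cv_folds = 10, cv_repeats = 3,
                        n_trees = 500, mtry_grid = NULL, gate_cutoff = 0.75,
                        index_mode = "rescaled", alpha = 0.05,
                        fdr_method = "BH", min_rin = 6, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(pert, "perturbation_table"))
  de_scope <- match.arg(de_scope)
  say <- function(...) if (verbose) message(sprintf(...))

  pre <- preprocess_cohort(expr, meta, min_rin = min_rin)
  say("preprocessed: %d genes x %d samples retained",
      nrow(pre$expr), ncol(pre$expr))
  universe <- colnames(pert$folds)

  cells <- unique(pre$meta[, c("tissue", "gender")])
  datasets <- list()
  models <- list()
  i <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (yb in young_bins) {
      if (identical(yb, old_bin)) next
      ds <- assemble_comparison(
        pre$partition, cells$tissue[ci], cells$gender[ci], yb, old_bin,
        universe, min_n, abundance_drop,
        de_alpha = if (de_scope == "comparison") de_alpha else Inf
      )
      if (is.null(ds)) next
      i <- i + 1L
      key <- paste(ds$tissue, ds$gender, ds$young_bin, sep = "|")
      fit <- tryCatch(
        age_classifier(
          ds, train_fraction = train_fraction, cv_folds = cv_folds,
          cv_repeats = cv_repeats, n_trees = n_trees, mtry_grid = mtry_grid,
          de_alpha = if (de_scope == "train") de_alpha else NULL,
          seed = derive_seed(seed, 500L + i)
        ),
        error = function(e) {
          say("comparison %s skipped: %s", key, conditionMessage(e))
          NULL
        }
      )
      if (is.null(fit)) next
      datasets[[key]] <- ds
      models[[key]] <- fit
      say("model %s: %d genes, gate %s", key, length(ds$genes),
          if (passes_gate(models[[key]], gate_cutoff)) "PASS" else "fail")
    }
  }

  passing <- select_models(models, gate_cutoff)
  counts <- list(
    n_samples = ncol(pre$expr), n_genes = nrow(pre$expr),
    n_comparisons = length(models), n_passing = length(passing),
    n_drugs = length(unique(pert$meta$drug)),
    n_instances = nrow(pert$folds)
  )
  params <- list(
    old_bin = old_bin, young_bins = young_bins, min_n = min_n,
    abundance_drop = abundance_drop, de_alpha = de_alpha,
    de_scope = de_scope,
    train_fraction = train_fraction, cv_folds = cv_folds,
    cv_repeats = cv_repeats, n_trees = n_trees, gate_cutoff = gate_cutoff,
    index_mode = index_mode, alpha = alpha, fdr_method = fdr_method,
    min_rin = min_rin, seed = seed
  )

  if (length(passing) == 0L) {
    return(structure(list(
      status = "no_passing_models", models = models,
      passing = character(0), report = models_report(models, gate_cutoff),
      index = NULL, cutoff = NA_real_,
      ranking = data.frame(), candidates = character(0),
      counts = counts, params = params
    ), class = "gero_screen"))
  }

  profiles <- lapply(names(passing), function(k) {
    middle_age_profile(datasets[[k]], passing[[k]]$genes)
  })
  names(profiles) <- names(passing)
  prob_inst <- classify_perturbations(passing, profiles, pert)
  prob_drug <- consolidate_per_drug(prob_inst, pert$meta$drug)
  index <- geroprotective_index(prob_drug, index_mode)

  cutoff <- mad_cutoff(index)
  cnt <- count_supporting_models(index, cutoff)
  N <- sum(!is.na(index))
  K <- sum(index > cutoff, na.rm = TRUE)
  pq <- enrichment_pvalues(cnt$k, cnt$M, N, K, fdr_method)
  ranking <- rank_drugs(cnt, pq, alpha)

  structure(list(
    status = "ok", models = models, passing = names(passing),
    report = models_report(models, gate_cutoff),
    probabilities = prob_drug, index = index, cutoff = cutoff,
    pooled = list(N = N, K = K),
    ranking = ranking,
    candidates = ranking$drug[ranking$significant],
    counts = counts, params = params
  ), class = "gero_screen")
}

#' @export
print.gero_screen <- function(x, ...) {
  cat("geroprotector screen\n")
  cat(sprintf("  %d samples, %d genes after preprocessing\n",
              x$counts$n_samples, x$counts$n_genes))
  cat(sprintf("  %d comparisons trained, %d models passed the %.2f gate\n",
              x$counts$n_comparisons, x$counts$n_passing,
              x$params$gate_cutoff))
  if (x$status == "no_passing_models") {
    cat("  status: no models passed the quality gate; no ranking produced\n")
    return(invisible(x))
  }
  cat(sprintf("  %d drugs x %d models scored; MAD cutoff %.4f (N=%d, K=%d)\n",
              nrow(x$index), ncol(x$index), x$cutoff,
              x$pooled$N, x$pooled$K))
  cat(sprintf("  %d candidate drug(s) at q <= %.2f\n",
              length(x$candidates), x$params$alpha))
  invisible(x)
}

#' @export
summary.gero_screen <- function(object, ...) {
  print(object)
  if (object$status == "ok" && nrow(object$ranking) > 0) {
    cat("\ntop of the ranking:\n")
    print(utils::head(object$ranking, 10), row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Simulate a cohort + perturbations and run the screen
#'
#' Convenience wrapper for fully synthetic runs: generates the cohort,
#' derives the planted aging signature (youngest vs old medians of the
#' processed cohort, restricted to the planted aging genes), generates
#' the perturbation table, and runs [gero_screen()].
#'
#' @param cohort_cfg a [cohort_config()]; its seed is re-derived from
#'   `seed`.
#' @param pert_cfg a [perturbation_config()]; likewise.
#' @param seed global seed.
#' @param ... further arguments to [gero_screen()].
#' @return a `gero_screen` object with an extra `truth` element (planted
#'   drug roles).
#' @export
synthetic_screen <- function(cohort_cfg = cohort_config(),
                             pert_cfg = perturbation_config(),
                             seed = 1L, ...) {
  cohort_cfg$seed <- derive_seed(seed, 1L)
  pert_cfg$seed <- derive_seed(seed, 2L)
  cohort <- generate_cohort(cohort_cfg)

  # signature on the processed scale, aging genes only
  pre <- preprocess_cohort(cohort$expr, cohort$meta)
  sig <- aging_signature(pre$expr, pre$meta,
                         young_bin = cohort_cfg$age_bins[1],
                         old_bin = cohort_cfg$age_bins[length(cohort_cfg$age_bins)])
  aging_genes <- cohort$gene_info$gene[cohort$gene_info$aging]
  sig_aging <- sig[sig$gene %in% aging_genes, , drop = FALSE]
  if (nrow(sig_aging) == 0L) {
    # no planted trend (e.g. a null screen): fall back to noise-only folds
    sig_aging <- sig[seq_len(min(1L, nrow(sig))), , drop = FALSE]
    pert_cfg$reversal_strength <- 0
  }
  pert <- generate_perturbations(pert_cfg, sig_aging,
                                 genes = rownames(cohort$expr))

  res <- gero_screen(cohort$expr, cohort$meta, pert$table,
                     old_bin = cohort_cfg$age_bins[length(cohort_cfg$age_bins)],
                     young_bins = utils::head(cohort_cfg$age_bins, -1),
                     seed = derive_seed(seed, 3L), ...)
  res$truth <- pert$truth
  res
}

#' Execute a screen run and write its artifacts to a directory
#'
#' Synthetic-mode pipeline driver: simulates the inputs, runs the screen,
#' and writes the models report, the drug x model index matrix, the
#' ranking, the candidate list and a provenance manifest (config, seed,
#' package version, per-stage counts). Rerunning with the same config and
#' seed reproduces identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort_cfg,pert_cfg synthetic input configurations.
#' @param seed global seed.
#' @param ... further arguments to [gero_screen()].
#' @return the `gero_screen` object, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_screen <- function(out_dir, cohort_cfg = cohort_config(),
                       pert_cfg = perturbation_config(), seed = 1L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- synthetic_screen(cohort_cfg, pert_cfg, seed = seed, ...)

  utils::write.csv(res$report, file.path(out_dir, "models_report.csv"),
                   row.names = FALSE)
  if (res$status == "ok") {
    utils::write.csv(data.frame(drug = rownames(res$index), res$index,
                                check.names = FALSE),
                     file.path(out_dir, "geroprotective_index.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    writeLines(res$candidates, file.path(out_dir, "candidates.txt"))
  }
  manifest <- list(
    package = "geroscreen",
    version = as.character(utils::packageVersion("geroscreen")),
    seed = seed, status = res$status,
    cohort_config = unclass(cohort_cfg),
    perturbation_config = unclass(pert_cfg),
    params = res$params, counts = res$counts,
    cutoff = res$cutoff
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
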