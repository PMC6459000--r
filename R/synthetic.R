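#' Configuration for a synthetic age-stratified expression cohort
#'
#' Describes a cohort in which a subset of genes carries a planted monotone
#' age trend on the log2 scale, linear in the age-bin index, with half of the
#' aging genes going up and half going down with age. Expression is emitted
#' as linear, nonnegative RPKM-like values (lognormal around a per-gene
#' baseline) so the full preprocessing path (normalise, filter, log) is
#' exercised.
#'
#' @param n_genes total number of genes.
#' @param n_aging_genes genes with a planted age trend (first
#'   `n_aging_genes` ids).
#' @param tissues,genders character vectors of labels.
#' @param age_bins ordered decade labels, youngest first.
#' @param samples_per_cell donors per (tissue, gender, age bin) cell.
#' @param effect_size standardized mean shift per decade step, in units of
#'   the within-bin SD.
#' @param noise_sd within-bin SD of log2 expression.
#' @param baseline_log2_range interval from which per-gene baseline log2
#'   means are drawn.
#' @param low_quality_frac fraction of samples given RIN < 6 or
#'   usable = FALSE, to exercise quality gating.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 1000, n_aging_genes = 100,
                          tissues = paste0("tissue_", 1:4),
                          genders = "male",
                          age_bins = c("20-29", "30-39", "40-49", "60-69"),
                          samples_per_cell = 30,
                          effect_size = 2, noise_sd = 0.5,
                          baseline_log2_range = c(1, 6),
                          low_quality_frac = 0.05,
                          seed = 1L) {
  if (samples_per_cell < 1) stop("samples_per_cell must be >= 1")
  if (n_aging_genes < 0 || n_aging_genes > n_genes) {
    stop("need 0 <= n_aging_genes <= n_genes")
  }
  if (effect_size < 0 || noise_sd <= 0) {
    stop("effect_size must be >= 0 and noise_sd > 0")
  }
  if (low_quality_frac < 0 || low_quality_frac >= 1) {
    stop("low_quality_frac must be in [0, 1)")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_aging_genes = as.integer(n_aging_genes),
    tissues = tissues, genders = genders, age_bins = age_bins,
    samples_per_cell = as.integer(samples_per_cell),
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_log2_range = baseline_log2_range,
    low_quality_frac = low_quality_frac, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic age-stratified cohort
#'
#' Aging genes have their expected log2 expression shifted by
#' `effect_size * noise_sd * bin_index` relative to the youngest bin, with a
#' fixed per-gene direction (first half up, second half down). Non-aging
#' genes are age-independent. A small fraction of samples receives RIN < 6
#' or a non-usable flag.
#'
#' @param config a [cohort_config()].
#' @return list with elements `expr` (linear genes x samples matrix),
#'   `meta` (sample metadata data.frame: `sample`, `tissue`, `gender`,
#'   `age_bin`, `rin`, `usable`) and `gene_info` (per-gene baseline,
#'   aging flag, trend direction).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 1L))
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  baseline <- stats::runif(config$n_genes, config$baseline_log2_range[1],
                           config$baseline_log2_range[2])
  aging <- seq_len(config$n_genes) <= config$n_aging_genes
  direction <- numeric(config$n_genes)
  if (config$n_aging_genes > 0) {
    half <- ceiling(config$n_aging_genes / 2)
    direction[seq_len(config$n_aging_genes)] <-
      rep(c(1, -1), c(half, config$n_aging_genes - half))
  }

  cells <- expand.grid(age_bin = config$age_bins, gender = config$genders,
                       tissue = config$tissues, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n_samples <- nrow(cells) * config$samples_per_cell
  meta <- data.frame(
    sample = sprintf("S%05d", seq_len(n_samples)),
    tissue = rep(cells$tissue, each = config$samples_per_cell),
    gender = rep(cells$gender, each = config$samples_per_cell),
    age_bin = rep(cells$age_bin, each = config$samples_per_cell),
    stringsAsFactors = FALSE
  )
  bin_index <- match(meta$age_bin, config$age_bins) - 1L

  # log2-scale means: baseline + direction * effect * sd * bin index
  shift <- outer(direction * config$effect_size * config$noise_sd, bin_index)
  mu <- baseline + shift
  log2_expr <- mu + matrix(stats::rnorm(config$n_genes * n_samples,
                                        sd = config$noise_sd),
                           config$n_genes, n_samples)
  expr <- 2^log2_expr
  dimnames(expr) <- list(genes, meta$sample)

  meta$rin <- stats::runif(n_samples, 6, 10)
  meta$usable <- TRUE
  n_bad <- round(config$low_quality_frac * n_samples)
  if (n_bad > 0) {
    bad <- sample.int(n_samples, n_bad)
    low_rin <- bad[seq_len(ceiling(n_bad / 2))]
    meta$rin[low_rin] <- stats::runif(length(low_rin), 4, 5.9)
    meta$usable[setdiff(bad, low_rin)] <- FALSE
  }

  list(
    expr = set_stage(expr, "linear"),
    meta = meta,
    gene_info = data.frame(gene = genes, baseline_log2 = baseline,
                           aging = aging, direction = direction,
                           stringsAsFactors = FALSE)
  )
}

#' Summarise the planted aging signature of a processed cohort
#'
#' Computes the per-gene median post-log expression in the youngest and the
#' old age bin (pooled over tissues and genders); the young/old medians are
#' the reference profiles against which perturbation fold changes are
#' defined.
#'
#' @param expr post-log genes x samples matrix.
#' @param meta matching sample metadata.
#' @param young_bin,old_bin age-bin labels to contrast.
#' @return data.frame with columns `gene`, `young`, `old` (median log2
#'   expression) and `delta` (`old - young`).
#' @export
aging_signature <- function(expr, meta, young_bin, old_bin = "60-69") {
  assert_stage(expr, "log2", "aging_signature()")
  meta <- meta[match(colnames(expr), meta$sample), ]
  y <- expr[, meta$age_bin == young_bin, drop = FALSE]
  o <- expr[, meta$age_bin == old_bin, drop = FALSE]
  if (ncol(y) == 0L || ncol(o) == 0L) {
    stop("no samples in one of the requested age bins")
  }
  data.frame(
    gene = rownames(expr),
    young = apply(y, 1, stats::median),
    old = apply(o, 1, stats::median),
    delta = apply(o, 1, stats::median) - apply(y, 1, stats::median),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic drug-perturbation table
#'
#' @param n_drugs total number of distinct compounds.
#' @param n_rejuvenating,n_proaging planted rejuvenating / pro-aging drugs;
#'   the remainder are neutral.
#' @param instances_per_drug replicate instances (cell lines / doses) per
#'   drug.
#' @param reversal_strength fraction of the planted aging trend reversed
#'   (0-1; > 1 over-corrects).
#' @param fold_noise_sd SD of log2 fold-change noise applied to every gene.
#' @param seed integer seed.
#' @return a `perturbation_config` list.
#' @export
perturbation_config <- function(n_drugs = 200, n_rejuvenating = 10,
                                n_proaging = 10, instances_per_drug = 3,
                                reversal_strength = 1, fold_noise_sd = 0.1,
                                seed = 1L) {
  if (n_rejuvenating + n_proaging > n_drugs) {
    stop("n_rejuvenating + n_proaging must be <= n_drugs")
  }
  if (reversal_strength < 0) stop("reversal_strength must be >= 0")
  if (fold_noise_sd < 0) stop("fold_noise_sd must be >= 0")
  structure(list(
    n_drugs = as.integer(n_drugs),
    n_rejuvenating = as.integer(n_rejuvenating),
    n_proaging = as.integer(n_proaging),
    instances_per_drug = as.integer(instances_per_drug),
    reversal_strength = reversal_strength, fold_noise_sd = fold_noise_sd,
    seed = as.integer(seed)
  ), class = "perturbation_config")
}

#' Generate a synthetic perturbation table with ground-truth labels
#'
#' Rejuvenating drugs carry linear fold changes that move the aging genes of
#' a middle-age profile toward the young median by
#' `reversal_strength * (old - young)/2` on the log2 scale; pro-aging drugs
#' move them toward old; neutral drugs carry only noise. Folds are exact with
#' respect to the signature's own middle-age profile: for target post-log
#' value `t` and middle value `m`, `f = (2^t - 1) / (2^m - 1)`.
#'
#' @param config a [perturbation_config()].
#' @param signature data.frame from [aging_signature()] restricted to the
#'   planted aging genes (the targets); must be nonempty.
#' @param genes full gene universe for the fold-change columns (defaults to
#'   the signature genes).
#' @return list with `table` (a `perturbation_table`: `meta` data.frame +
#'   `folds` instances x genes matrix, linear scale) and `truth`
#'   (data.frame `drug`, `role`).
#' @export
generate_perturbations <- function(config, signature, genes = signature$gene) {
  stopifnot(inherits(config, "perturbation_config"))
  if (is.null(signature) || nrow(signature) == 0L) {
    stop("cannot generate reversal folds from an empty aging signature")
  }
  if (!all(signature$gene %in% genes)) {
    stop("signature genes must be a subset of the gene universe")
  }
  set.seed(derive_seed(config$seed, 2L))

  drugs <- sprintf("drug_%03d", seq_len(config$n_drugs))
  role <- rep("neutral", config$n_drugs)
  role[seq_len(config$n_rejuvenating)] <- "rejuvenating"
  if (config$n_proaging > 0) {
    role[config$n_rejuvenating + seq_len(config$n_proaging)] <- "proaging"
  }
  truth <- data.frame(drug = drugs, role = role, stringsAsFactors = FALSE)

  n_inst <- config$n_drugs * config$instances_per_drug
  meta <- data.frame(
    instance = sprintf("inst_%04d", seq_len(n_inst)),
    drug = rep(drugs, each = config$instances_per_drug),
    cell_line = sample(c("MCF7", "PC3", "HL60"), n_inst, replace = TRUE),
    dose = sample(c("100nM", "1uM", "10uM"), n_inst, replace = TRUE),
    duration = sample(c("6h", "12h"), n_inst, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # noise folds on every gene
  folds <- matrix(2^stats::rnorm(n_inst * length(genes),
                                 sd = config$fold_noise_sd),
                  n_inst, length(genes), dimnames = list(meta$instance, genes))

  # deterministic signal folds on the signature genes
  mid <- (signature$young + signature$old) / 2
  x_mid <- 2^mid - 1
  signal_fold <- function(sign_dir) {
    target <- mid - sign_dir * config$reversal_strength *
      (signature$old - signature$young) / 2
    f <- ifelse(x_mid > 1e-12, (2^pmax(target, 0) - 1) / x_mid, 1)
    pmax(f, 1e-9)
  }
  f_rej <- signal_fold(+1)   # toward young
  f_pro <- signal_fold(-1)   # toward old
  sig_cols <- match(signature$gene, genes)
  inst_role <- rep(role, each = config$instances_per_drug)
  if (any(inst_role == "rejuvenating")) {
    folds[inst_role == "rejuvenating", sig_cols] <-
      sweep(folds[inst_role == "rejuvenating", sig_cols, drop = FALSE],
            2, f_rej, `*`)
  }
  if (any(inst_role == "proaging")) {
    folds[inst_role == "proaging", sig_cols] <-
      sweep(folds[inst_role == "proaging", sig_cols, drop = FALSE],
            2, f_pro, `*`)
  }

  list(
    table = structure(list(meta = meta, folds = folds),
                      class = "perturbation_table"),
    truth = truth
  )
}

#' @export
print.perturbation_table <- function(x, ...) {
  cat(sprintf("perturbation table: %d instances x %d genes, %d drugs\n",
              nrow(x$folds), ncol(x$folds), length(unique(x$meta$drug))))
  invisible(x)
}

#' Build a known-geroprotector reference set from ground-truth labels
#'
#' Emulates a curated lifespan-extension database: a subset of the true
#' rejuvenators plus a controllable fraction of neutral decoys.
#'
#' @param truth data.frame (`drug`, `role`) from [generate_perturbations()].
#' @param contamination decoys added as a fraction of the included true
#'   rejuvenators, in \[0, 1\].
#' @param n_true number of true rejuvenators to include (default: all).
#' @param seed integer seed.
#' @return character vector of drug names with attribute `source = "synthetic"`.
#' @export
generate_known_set <- function(truth, contamination = 0, n_true = NULL,
                               seed = 1L) {
  if (contamination < 0 || contamination > 1) {
    stop("contamination must be in [0, 1]")
  }
  rej <- truth$drug[truth$role == "rejuvenating"]
  neutral <- truth$drug[truth$role == "neutral"]
  if (length(rej) == 0L) {
    return(structure(character(0), source = "synthetic"))
  }
  set.seed(derive_seed(seed, 3L))
  if (is.null(n_true)) n_true <- length(rej)
  n_true <- min(n_true, length(rej))
  chosen <- sample(rej, n_true)
  n_decoy <- min(round(contamination * n_true), length(neutral))
  decoys <- if (n_decoy > 0) sample(neutral, n_decoy) else character(0)
  structure(sort(c(chosen, decoys)), source = "synthetic")
}

#' Configuration for a synthetic worm lifespan-machine experiment
#'
#' Mortality follows a Weibull law (a convenient heavy-right-tail stand-in
#' for Gompertz-like worm mortality) with a per-arm median of
#' `median_control_lifespan * multiplier`. Worm positions follow per-worm
#' random walks on an integer pixel grid; each frame a living worm moves
#' with probability `2^(-t / (activity_halflife * multiplier))` (activity
#' decays with age, scaled with the arm's lifespan) and freezes at death.
#'
#' @param n_worms_per_arm worms per treatment arm (default profiles keep
#'   this at >= 50, the minimum for a reportable lifespan curve).
#' @param arms named numeric vector of lifespan-scale multipliers (> 0).
#' @param shape Weibull shape parameter.
#' @param median_control_lifespan control median lifespan in days.
#' @param censor_prob per-worm probability of right censoring.
#' @param arena grid dimensions in pixels, `c(width, height)`.
#' @param frames_per_day position snapshots per day.
#' @param activity_halflife days for the movement probability to halve in
#'   the control arm.
#' @param plates_per_arm plates each arm's worms are spread over.
#' @param step_sd SD (pixels) of each random-walk step when a worm moves.
#' @param seed integer seed.
#' @return a `worm_config` list.
#' @export
worm_config <- function(n_worms_per_arm = 100,
                        arms = c(control = 1),
                        shape = 4, median_control_lifespan = 20,
                        censor_prob = 0, arena = c(64, 64),
                        frames_per_day = 1, activity_halflife = 4,
                        plates_per_arm = 2, step_sd = 3, seed = 1L) {
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    stop("arms must be a named vector of multipliers")
  }
  if (any(arms <= 0)) stop("arm multipliers must be > 0")
  if (censor_prob < 0 || censor_prob > 1) stop("censor_prob must be in [0,1]")
  if (n_worms_per_arm < 1) stop("n_worms_per_arm must be >= 1")
  structure(list(
    n_worms_per_arm = as.integer(n_worms_per_arm), arms = arms,
    shape = shape, median_control_lifespan = median_control_lifespan,
    censor_prob = censor_prob, arena = as.integer(arena),
    frames_per_day = frames_per_day, activity_halflife = activity_halflife,
    plates_per_arm = as.integer(plates_per_arm), step_sd = step_sd,
    seed = as.integer(seed)
  ), class = "worm_config")
}

#' Generate synthetic worm survival and position logs
#'
#' @param config a [worm_config()].
#' @return list with `survival` (data.frame `worm`, `arm`, `plate`, `day`,
#'   `censored`) and `positions` (data.frame `plate`, `timepoint`, `worm`,
#'   `x`, `y`; integer pixel coordinates, frozen after death, absent after
#'   censoring).
#' @export
generate_worm_experiment <- function(config) {
  stopifnot(inherits(config, "worm_config"))
  set.seed(derive_seed(config$seed, 4L))
  scale0 <- config$median_control_lifespan / log(2)^(1 / config$shape)

  surv <- list()
  pos <- list()
  for (a in seq_along(config$arms)) {
    arm <- names(config$arms)[a]
    mult <- config$arms[[a]]
    n <- config$n_worms_per_arm
    death <- stats::rweibull(n, shape = config$shape, scale = scale0 * mult)
    censored <- stats::runif(n) < config$censor_prob
    obs <- ifelse(censored, stats::runif(n) * death, death)
    obs <- pmax(round(obs, 2), 0.01)
    plate <- sprintf("%s_p%d", arm,
                     rep_len(seq_len(config$plates_per_arm), n))
    worm_id <- sprintf("%s_w%04d", arm, seq_len(n))
    surv[[arm]] <- data.frame(worm = worm_id, arm = arm, plate = plate,
                              day = obs, censored = as.integer(censored),
                              stringsAsFactors = FALSE)

    # random-walk position log; movement probability halves every
    # activity_halflife * multiplier days, positions freeze at death
    halflife <- config$activity_halflife * mult
    t_max <- ceiling(max(obs))
    times <- seq(1 / config$frames_per_day, t_max,
                 by = 1 / config$frames_per_day)
    x <- stats::runif(n, 1, config$arena[1])
    y <- stats::runif(n, 1, config$arena[2])
    frames <- vector("list", length(times))
    for (ti in seq_along(times)) {
      t <- times[ti]
      alive <- obs >= t
      p_move <- 2^(-t / halflife)
      moves <- alive & (stats::runif(n) < p_move)
      if (any(moves)) {
        x[moves] <- pmin(pmax(x[moves] +
                                stats::rnorm(sum(moves), sd = config$step_sd),
                              1), config$arena[1])
        y[moves] <- pmin(pmax(y[moves] +
                                stats::rnorm(sum(moves), sd = config$step_sd),
                              1), config$arena[2])
      }
      present <- !censored | (obs >= t)   # censored worms leave the log
      frames[[ti]] <- data.frame(
        plate = plate[present], timepoint = t, worm = worm_id[present],
        x = as.integer(round(x[present])), y = as.integer(round(y[present])),
        stringsAsFactors = FALSE
      )
    }
    pos[[arm]] <- do.call(rbind, frames)
  }

  list(
    survival = do.call(rbind, c(surv, list(make.row.names = FALSE))),
    positions = do.call(rbind, c(pos, list(make.row.names = FALSE)))
  )
}
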