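test_that("cohort generation is a pure function of its config", {
  cfg <- cohort_config(n_genes = 80, n_aging_genes = 8, tissues = "liver",
                       age_bins = c("20-29", "60-69"), samples_per_cell = 5,
                       seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$meta, b$meta)
})

test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(samples_per_cell = 0), "samples_per_cell")
  expect_error(cohort_config(n_genes = 10, n_aging_genes = 11), "n_aging_genes")
})

test_that("a null cohort is calibrated: ~1% of genes reject at alpha = 0.01", {
  cfg <- cohort_config(n_genes = 2000, n_aging_genes = 0, tissues = "liver",
                       genders = "male", age_bins = c("20-29", "60-69"),
                       samples_per_cell = 30, effect_size = 0,
                       low_quality_frac = 0, seed = 5)
  cohort <- generate_cohort(cfg)
  x <- log_transform(cohort$expr)
  young <- x[, cohort$meta$age_bin == "20-29"]
  old <- x[, cohort$meta$age_bin == "60-69"]
  frac <- nrow(differential_filter(young, old, alpha = 0.01)) / nrow(x)
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.03)
})

test_that("planted aging genes are recovered by the differential filter", {
  cfg <- cohort_config(n_genes = 500, n_aging_genes = 100, tissues = "liver",
                       genders = "male",
                       age_bins = c("20-29", "30-39", "40-49", "60-69"),
                       samples_per_cell = 30, effect_size = 2, noise_sd = 0.5,
                       low_quality_frac = 0, seed = 3)
  cohort <- generate_cohort(cfg)
  x <- log_transform(cohort$expr)
  young <- x[, cohort$meta$age_bin == "20-29"]
  old <- x[, cohort$meta$age_bin == "60-69"]
  surviving <- differential_filter(young, old, alpha = 0.01)$gene
  aging <- cohort$gene_info$gene[cohort$gene_info$aging]
  expect_gt(mean(aging %in% surviving), 0.9)
})

test_that("perturbation tables have the right shape and exact reversal folds", {
  cfg <- cohort_config(n_genes = 150, n_aging_genes = 20, tissues = "liver",
                       genders = "male", age_bins = c("20-29", "60-69"),
                       samples_per_cell = 15, low_quality_frac = 0, seed = 2)
  cohort <- generate_cohort(cfg)
  pre <- preprocess_cohort(cohort$expr, cohort$meta)
  sig <- aging_signature(pre$expr, pre$meta, "20-29", "60-69")
  sig <- sig[sig$gene %in% cohort$gene_info$gene[cohort$gene_info$aging], ]

  pcfg <- perturbation_config(n_drugs = 200, n_rejuvenating = 5,
                              n_proaging = 5, instances_per_drug = 3,
                              reversal_strength = 1, fold_noise_sd = 0,
                              seed = 9)
  pert <- generate_perturbations(pcfg, sig, genes = rownames(pre$expr))
  expect_equal(nrow(pert$table$folds), 600)   # 200 drugs x 3 instances

  # noiseless full reversal: induced transcriptome == young median exactly
  mid <- stats::setNames((sig$young + sig$old) / 2, sig$gene)
  inst <- which(pert$table$meta$drug == "drug_001")[1]
  induced <- apply_fold_changes(mid, pert$table$folds[inst, ])
  expect_equal(unname(induced), sig$young, tolerance = 1e-9)

  # pro-aging moves toward the old median
  inst_pro <- which(pert$table$meta$drug == "drug_006")[1]
  induced_pro <- apply_fold_changes(mid, pert$table$folds[inst_pro, ])
  expect_equal(unname(induced_pro), sig$old, tolerance = 1e-9)
})

test_that("reversal on an empty signature is rejected", {
  cfg <- perturbation_config(n_drugs = 4, n_rejuvenating = 1, n_proaging = 0)
  empty <- data.frame(gene = character(0), young = numeric(0),
                      old = numeric(0), delta = numeric(0))
  expect_error(generate_perturbations(cfg, empty), "empty")
})

test_that("known-set generation respects contamination", {
  truth <- data.frame(
    drug = sprintf("drug_%03d", 1:30),
    role = rep(c("rejuvenating", "proaging", "neutral"), c(5, 5, 20))
  )
  rej <- truth$drug[truth$role == "rejuvenating"]

  clean <- generate_known_set(truth, contamination = 0, seed = 1)
  expect_true(all(clean %in% rej))

  dirty <- generate_known_set(truth, contamination = 1, seed = 1)
  expect_length(dirty, 10)                       # 5 true + 5 decoys
  expect_equal(sum(dirty %in% rej), 5)
  expect_equal(sum(dirty %in% truth$drug[truth$role == "neutral"]), 5)

  none <- generate_known_set(truth[truth$role == "neutral", ], 0.5, seed = 1)
  expect_length(none, 0)

  expect_error(generate_known_set(truth, contamination = 1.5), "contamination")
})

test_that("worm experiments are deterministic and honour the censoring switch", {
  cfg <- worm_config(n_worms_per_arm = 60, arms = c(control = 1),
                     censor_prob = 0, frames_per_day = 1, seed = 4)
  a <- generate_worm_experiment(cfg)
  b <- generate_worm_experiment(cfg)
  expect_identical(a, b)
  expect_true(all(a$survival$censored == 0))
  expect_true(all(a$survival$day > 0))

  cfg2 <- worm_config(n_worms_per_arm = 200, censor_prob = 0.3, seed = 4)
  w2 <- generate_worm_experiment(cfg2)
  expect_gt(sum(w2$survival$censored), 0)
})

test_that("a 1.25x arm has ~1.25x empirical median lifespan", {
  cfg <- worm_config(n_worms_per_arm = 500,
                     arms = c(control = 1, treated = 1.25),
                     frames_per_day = 1, seed = 8)
  w <- generate_worm_experiment(cfg)
  med <- tapply(w$survival$day, w$survival$arm, stats::median)
  ratio <- med[["treated"]] / med[["control"]]
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.35)
})

test_that("positions freeze after the whole population is dead", {
  cfg <- worm_config(n_worms_per_arm = 50, arms = c(control = 1),
                     median_control_lifespan = 6, frames_per_day = 1,
                     plates_per_arm = 1, seed = 6)
  w <- generate_worm_experiment(cfg)
  d <- max(w$survival$day)
  after <- w$positions[w$positions$timepoint > d, ]
  if (nrow(after) > 0) {
    by_worm <- split(after, after$worm)
    moved <- vapply(by_worm, function(p) {
      length(unique(p$x)) > 1 || length(unique(p$y)) > 1
    }, logical(1))
    expect_false(any(moved))
  } else {
    succeed("no frames recorded beyond the last death")
  }
})
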