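test_that("the differential filter matches the equal-variance t-test", {
  young <- make_expr(c(0, 0, 0, 0), 1, 4, stage = "log2")
  old <- make_expr(c(5, 5, 5, 5.1), 1, 4, stage = "log2")
  rownames(old) <- rownames(young)
  expect_identical(differential_filter(young, old, 0.01)$gene, "g001")

  # identical constant gene across both groups is dropped even at alpha = 1
  yc <- make_expr(rep(2, 4), 1, 4); oc <- make_expr(rep(2, 4), 1, 4)
  expect_equal(nrow(differential_filter(yc, oc, 1)), 0)

  # p values agree with stats::t.test(var.equal = TRUE) on random genes
  set.seed(1)
  y <- make_expr(stats::rnorm(20 * 6), 20, 6)
  o <- make_expr(stats::rnorm(20 * 8, mean = 0.5), 20, 8)
  got <- differential_filter(y, o, alpha = 1)
  oracle <- vapply(seq_len(20), function(i) {
    stats::t.test(y[i, ], o[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(got$p, oracle[oracle < 1][match(got$gene, rownames(y)[oracle < 1])],
               tolerance = 1e-12)
  expect_equal(nrow(got), 20)   # alpha = 1: every testable gene survives
})

test_that("comparison assembly enforces the minimum-n and universe rules", {
  set.seed(2)
  genes <- sprintf("g%03d", 1:20)
  young <- matrix(stats::rnorm(20 * 9, 5), 20, 9,
                  dimnames = list(genes, paste0("y", 1:9)))
  old <- matrix(stats::rnorm(20 * 12, 5), 20, 12,
                dimnames = list(genes, paste0("o", 1:12)))
  part <- list("liver|male|20-29" = young, "liver|male|60-69" = old)

  # young side n = 9 < 10 -> skip signal, not an error
  expect_null(assemble_comparison(part, "liver", "male", "20-29",
                                  universe = genes))

  part10 <- part
  part10[["liver|male|20-29"]] <- cbind(young, y10 = stats::rnorm(20, 5))
  ds <- assemble_comparison(part10, "liver", "male", "20-29",
                            universe = genes[1:15], abundance_drop = 0,
                            de_alpha = Inf)
  # genes outside the universe never appear
  expect_true(all(ds$genes %in% genes[1:15]))

  expect_error(assemble_comparison(part10, "liver", "male", "60-69",
                                   old_bin = "60-69", universe = genes),
               "differ")
})

test_that("the 10% abundance drop removes exactly the lowest-mean genes", {
  genes <- sprintf("g%03d", 1:20)
  base <- seq(2, 8, length.out = 20)           # g001, g002 have lowest means
  young <- matrix(rep(base, 10), 20, 10, dimnames = list(genes, paste0("y", 1:10)))
  old <- matrix(rep(base, 10), 20, 10, dimnames = list(genes, paste0("o", 1:10)))
  set.seed(3)
  young <- young + matrix(stats::rnorm(200, sd = 0.01), 20)
  old <- old + matrix(stats::rnorm(200, sd = 0.01), 20)
  part <- list("liver|male|20-29" = young, "liver|male|60-69" = old)
  ds <- assemble_comparison(part, "liver", "male", "20-29", universe = genes,
                            abundance_drop = 0.10, de_alpha = Inf)
  expect_length(ds$genes, 18)                  # floor(0.10 * 20) = 2 dropped
  expect_false(any(c("g001", "g002") %in% ds$genes))
})

test_that("training balances classes and is deterministic in the seed", {
  ds <- make_separable_dataset(n_per_side = 25, seed = 10)
  # imbalance: drop 10 young columns -> 15 young vs 25 old
  ds$young <- ds$young[, 1:15]
  m <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 1)
  expect_equal(m$n_per_class, 15)

  m2 <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 1)
  expect_identical(m$mtry, m2$mtry)
  expect_identical(predict(m, ds$young), predict(m2, ds$young))
  expect_identical(m$test, m2$test)
})

test_that("probabilities are bounded and the positive class is young", {
  ds <- make_separable_dataset(seed = 11)
  m <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 2)
  p_young <- predict(m, ds$young)
  p_old <- predict(m, ds$old)
  expect_true(all(p_young >= 0 & p_young <= 1))
  expect_gt(mean(p_young), mean(p_old))
})

test_that("a separable comparison trains to high held-out accuracy", {
  accs <- vapply(1:5, function(s) {
    ds <- make_separable_dataset(seed = 100 + s)
    age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = s)$test$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("label-permuted training gives chance-level CV ROC-AUC", {
  aucs <- vapply(1:3, function(s) {
    ds <- make_separable_dataset(seed = 200 + s, permute_labels = TRUE)
    age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = s)$cv$roc_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("evaluation needs both classes and counts accuracy at the 0.5 cut", {
  ds <- make_separable_dataset(n_per_side = 20, n_inf = 10, shift = 3,
                               seed = 12)
  m <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 3)
  expect_error(evaluate_classifier(m, ds$young[, 1:4], rep(TRUE, 4)),
               "single class")

  # 3 correct of 4: two clear young, one clear old, one old disguised as young
  newdata <- cbind(ds$young[, 1:2], ds$old[, 1], ds$young[, 3])
  colnames(newdata) <- c("a", "b", "c", "d")
  ev <- evaluate_classifier(m, newdata, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ev$accuracy, 0.75)
})

test_that("the quality gate demands all five metrics above the cutoff", {
  fake <- function(cv_auc, sens, spec, t_auc, acc) {
    structure(list(cv = list(roc_auc = cv_auc, sensitivity = sens,
                             specificity = spec),
                   test = list(roc_auc = t_auc, accuracy = acc)),
              class = "age_classifier")
  }
  good <- fake(0.8, 0.8, 0.8, 0.8, 0.8)
  bad <- fake(0.9, 0.9, 0.70, 0.9, 0.9)
  boundary <- fake(0.75, 0.9, 0.9, 0.9, 0.9)
  expect_true(passes_gate(good))
  expect_false(passes_gate(bad))
  expect_false(passes_gate(boundary))          # strictly above 0.75
  expect_length(select_models(list(good, bad, boundary)), 1)
  expect_length(select_models(list()), 0)
})

test_that("the held-out split never influences tuning", {
  ds <- make_separable_dataset(n_per_side = 20, seed = 13)
  m <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 4)
  # corrupt exactly the samples that ended up in the test split
  ds2 <- ds
  for (s in m$test_samples) {
    if (s %in% colnames(ds2$young)) ds2$young[, s] <- ds2$young[, s] + 100
    if (s %in% colnames(ds2$old)) ds2$old[, s] <- ds2$old[, s] + 100
  }
  m2 <- age_classifier(ds2, cv_folds = 5, cv_repeats = 1, seed = 4)
  expect_identical(m2$mtry, m$mtry)
  expect_equal(m2$cv, m$cv)
})
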