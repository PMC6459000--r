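test_that("the middle-age profile averages the young and old medians", {
  genes <- c("g001", "g002")
  young <- matrix(c(2, 2, 2, 1, 2, 3), 2, 3, byrow = TRUE,
                  dimnames = list(genes, paste0("y", 1:3)))
  old <- matrix(c(4, 4, 4, 2, 4, 6), 2, 3, byrow = TRUE,
                dimnames = list(genes, paste0("o", 1:3)))
  ds <- structure(list(genes = genes, young = young, old = old),
                  class = "age_dataset")
  prof <- middle_age_profile(ds)
  expect_equal(unname(prof), c(3, 3))          # (2+4)/2, (2+4)/2

  # young identical to old -> profile equals either median
  ds2 <- ds; ds2$old <- ds2$young
  expect_equal(unname(middle_age_profile(ds2)), c(2, 2))

  # single sample per side: plain average of the two values
  ds3 <- ds
  ds3$young <- ds$young[, 1, drop = FALSE]
  ds3$old <- ds$old[, 1, drop = FALSE]
  expect_equal(unname(middle_age_profile(ds3)), c(3, 1.5))

  expect_error(middle_age_profile(ds, genes = c("g001", "g999")), "g999")
})

test_that("probe collapsing takes the per-gene median", {
  map <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5", "p6"),
                    gene = c("gA", "gA", "gA", "gB", "gC", "gC"))
  folds <- c(p1 = 0.5, p2 = 1.0, p3 = 2.0, p4 = 0.8, p5 = 1, p6 = 3)
  out <- collapse_probes(folds, map)
  expect_equal(out[["gA"]], 1.0)
  expect_equal(out[["gB"]], 0.8)               # single probe -> itself
  expect_equal(out[["gC"]], 2)                 # even count: midpoint of {1, 3}

  m <- rbind(i1 = folds, i2 = folds * 2)
  mo <- collapse_probes(m, map)
  expect_equal(unname(mo["i2", "gA"]), 2.0)

  expect_error(collapse_probes(folds, map[0, ]), "empty")
  bad_map <- rbind(map, data.frame(probe = "p1", gene = "gZ"))
  expect_error(collapse_probes(folds, bad_map), "more than one")
})

test_that("fold application follows the linearise-multiply-relog convention", {
  prof <- c(gA = 1, gB = 0, gC = 2.5)

  # all-ones folds are the identity to machine precision
  same <- apply_fold_changes(prof, c(gA = 1, gB = 1, gC = 1))
  expect_equal(same, unname(prof) + numeric(3), ignore_attr = TRUE,
               tolerance = 1e-12)

  # v = 1 (x = 1), f = 3 -> x' = 3, v' = log2(4) = 2; v = 0 is a fixed point
  out <- apply_fold_changes(prof, c(gA = 3, gB = 7, gC = 1))
  expect_equal(unname(out[1]), 2)
  expect_equal(unname(out[2]), 0)

  expect_error(apply_fold_changes(prof, c(gA = 0, gB = 1, gC = 1)),
               "gA")
  expect_warning(apply_fold_changes(prof, c(gA = 2)), "missing")
})

test_that("round-trip linearise/relog with f = 1 is exact to 1e-12", {
  set.seed(20)
  v <- stats::runif(200, 0, 12)
  names(v) <- sprintf("g%03d", seq_along(v))
  f <- stats::setNames(rep(1, 200), names(v))
  expect_lt(max(abs(apply_fold_changes(v, f) - v)), 1e-12)
})

test_that("classification of all-ones folds reduces to the middle-age profile", {
  ds <- make_separable_dataset(n_per_side = 15, seed = 30)
  m <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 5)
  prof <- middle_age_profile(ds, m$genes)

  folds <- matrix(1, 2, length(ds$genes),
                  dimnames = list(c("i1", "i2"), ds$genes))
  pert <- structure(list(
    meta = data.frame(instance = c("i1", "i2"), drug = c("dA", "dB"),
                      cell_line = "MCF7", dose = "1uM", duration = "6h"),
    folds = folds), class = "perturbation_table")
  probs <- classify_perturbations(list(m1 = m), list(m1 = prof), pert)
  expect_equal(unname(probs[, "m1"]),
               rep(unname(predict(m, prof)), 2), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("instances missing most of a model's genes are flagged missing", {
  ds <- make_separable_dataset(n_per_side = 15, n_genes = 20, seed = 31)
  m <- age_classifier(ds, cv_folds = 5, cv_repeats = 1, seed = 6)
  prof <- middle_age_profile(ds, m$genes)
  few <- m$genes[seq_len(floor(length(m$genes) / 2))]   # exactly half covered
  folds <- matrix(1, 1, length(few), dimnames = list("i1", few))
  pert <- structure(list(
    meta = data.frame(instance = "i1", drug = "dA", cell_line = "x",
                      dose = "y", duration = "z"),
    folds = folds), class = "perturbation_table")
  probs <- classify_perturbations(list(m1 = m), list(m1 = prof), pert)
  expect_true(is.na(probs["i1", "m1"]))
})

test_that("per-drug consolidation takes the best instance", {
  prob <- matrix(c(0.3, 0.7, 0.6, 0.2, NA, 0.4), 3, 2,
                 dimnames = list(c("i1", "i2", "i3"), c("mA", "mB")))
  out <- consolidate_per_drug(prob, c("d1", "d1", "d1"))
  expect_equal(unname(out["d1", "mA"]), 0.7)
  expect_equal(unname(out["d1", "mB"]), 0.4)

  single <- consolidate_per_drug(prob[1, , drop = FALSE], "d1")
  expect_equal(unname(single["d1", "mA"]), 0.3)

  # adding a lower-probability instance never changes a cell
  more <- rbind(prob, i4 = c(0.1, 0.1))
  out2 <- consolidate_per_drug(more, rep("d1", 4))
  expect_equal(out2, out)

  # all instances missing for a model -> cell stays missing
  all_na <- matrix(NA_real_, 2, 1, dimnames = list(c("i1", "i2"), "mA"))
  expect_true(is.na(consolidate_per_drug(all_na, c("d1", "d1"))["d1", "mA"]))
})

test_that("the geroprotective index centers and rescales per model column", {
  prob <- cbind(mA = c(0.5, 0.6, 0.7))
  rownames(prob) <- paste0("d", 1:3)
  idx <- geroprotective_index(prob)
  expect_equal(unname(idx[, "mA"]), c(0, 0.25, 0.5))

  # extremes map to +/- 0.5; 0.5 maps to 0
  prob2 <- cbind(mA = c(0, 0.5, 1))
  expect_equal(unname(geroprotective_index(prob2)[, "mA"]), c(-0.5, 0, 0.5))

  # plain mode is p - 0.5
  expect_equal(unname(geroprotective_index(prob, "plain")[, "mA"]),
               c(0, 0.1, 0.2))

  # a column constant at 0.5 maps to all zeros
  const <- cbind(mA = rep(0.5, 4))
  expect_equal(unname(geroprotective_index(const)[, "mA"]), rep(0, 4))

  expect_error(geroprotective_index(cbind(mA = c(0.2, 1.3))), "\\[0, 1\\]")
})

test_that("the index is strictly increasing in probability within a column", {
  set.seed(21)
  prob <- matrix(stats::runif(60), 20, 3,
                 dimnames = list(paste0("d", 1:20), paste0("m", 1:3)))
  idx <- geroprotective_index(prob)
  for (j in 1:3) {
    expect_identical(order(idx[, j]), order(prob[, j]))
    expect_true(all((idx[, j] > 0) == (prob[, j] > 0.5)))
  }
  expect_true(all(idx >= -0.5 & idx <= 0.5))
})
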