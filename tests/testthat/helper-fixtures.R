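# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no data files.

# A linear-stage expression matrix with dimnames and stage flag.
make_expr <- function(values, n_genes, n_samples, stage = "linear") {
  x <- matrix(values, n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  attr(x, "stage") <- stage
  x
}

# A separable young-vs-old comparison: n_inf genes shifted by `shift` SD
# (unit SD noise), the rest pure noise. Returns an age_dataset built through
# the public assembly path (no abundance drop, no DE filter).
make_separable_dataset <- function(n_per_side = 30, n_genes = 50,
                                   n_inf = 5, shift = 2, seed = 1,
                                   permute_labels = FALSE) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  base <- stats::runif(n_genes, 3, 7)
  young <- matrix(stats::rnorm(n_genes * n_per_side, base), n_genes,
                  dimnames = list(genes, sprintf("y%03d", seq_len(n_per_side))))
  old <- matrix(stats::rnorm(n_genes * n_per_side, base), n_genes,
                dimnames = list(genes, sprintf("o%03d", seq_len(n_per_side))))
  if (n_inf > 0) old[seq_len(n_inf), ] <- old[seq_len(n_inf), ] + shift
  if (permute_labels) {
    pool <- cbind(young, old)
    idx <- sample(ncol(pool))
    young <- pool[, idx[seq_len(n_per_side)], drop = FALSE]
    old <- pool[, idx[n_per_side + seq_len(n_per_side)], drop = FALSE]
  }
  part <- list()
  attr(young, "stage") <- "log2"
  attr(old, "stage") <- "log2"
  part[["cortex|male|20-29"]] <- young
  part[["cortex|male|60-69"]] <- old
  assemble_comparison(part, "cortex", "male", "20-29", "60-69",
                      universe = genes, min_n = 2, abundance_drop = 0,
                      de_alpha = Inf)
}

# Small screen configs used by determinism / smoke tests.
small_cohort_cfg <- function(effect_size = 2, seed = 1) {
  cohort_config(n_genes = 300, n_aging_genes = 30,
                tissues = c("tissue_1", "tissue_2"), genders = "male",
                age_bins = c("20-29", "40-49", "60-69"),
                samples_per_cell = 15, effect_size = effect_size,
                noise_sd = 0.5, seed = seed)
}

small_pert_cfg <- function(reversal_strength = 1, seed = 1) {
  perturbation_config(n_drugs = 40, n_rejuvenating = 4, n_proaging = 4,
                      instances_per_drug = 2,
                      reversal_strength = reversal_strength, seed = seed)
}

# Upper-tail hypergeometric by exhaustive enumeration (independent oracle).
enum_hyper_upper <- function(k, N, K, M) {
  js <- k:min(M, K)
  js <- js[js >= max(0, M - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, M - js)) / choose(N, M)
}

# Hand step-up Benjamini-Hochberg (independent of p.adjust).
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Two-group log-rank chi-square computed directly from the O-E formula
# (independent of survival::survdiff).
hand_logrank <- function(days, events, group) {
  times <- sort(unique(days[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- days >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(days == t & events == 1)
    d1 <- sum(days == t & events == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}
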