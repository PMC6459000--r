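#' Mean-absolute-deviation cutoff of the consolidated index distribution
#'
#' The significance cutoff for counting supporting models: the mean over
#' all pooled index values of their absolute deviation from the pooled
#' mean. A model cell "supports" a drug iff its index strictly exceeds the
#' cutoff.
#'
#' @param values numeric vector or matrix of index values pooled across
#'   drugs and models; NAs ignored.
#' @return the cutoff (index units).
#' @export
mad_cutoff <- function(values) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no index values to pool")
  mean(abs(v - mean(v)))
}

#' Count supporting models per drug
#'
#' @param index drugs x models index matrix.
#' @param cutoff from [mad_cutoff()]; strict `>` (an index exactly at the
#'   cutoff does not count).
#' @return data.frame per drug: `k` (supporting models) and `M`
#'   (non-missing predictions for that drug).
#' @export
count_supporting_models <- function(index, cutoff) {
  data.frame(
    drug = rownames(index),
    k = as.integer(rowSums(index > cutoff, na.rm = TRUE)),
    M = as.integer(rowSums(!is.na(index))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Hypergeometric enrichment p values with FDR correction
#'
#' For a drug supported by k of its M model predictions, p is the upper
#' tail P(X >= k) of a hypergeometric draw of M from a population of N
#' pooled predictions containing K above-cutoff ones (k = 0 gives p = 1).
#' q values are Benjamini-Hochberg over all screened drugs by default.
#'
#' @param k per-drug supporting-model counts.
#' @param M per-drug number of (non-missing) predictions.
#' @param N total pooled predictions.
#' @param K total above-cutoff predictions.
#' @param method multiple-testing correction, `"BH"` (default) or `"BY"`.
#' @return data.frame with `p` and `q` in input order.
#' @export
enrichment_pvalues <- function(k, M, N, K, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (K > N) stop("inconsistent totals: K > N")
  if (any(k > pmin(M, K))) stop("inconsistent counts: k > min(M, K)")
  if (any(M > N)) stop("inconsistent totals: M > N")
  p <- stats::phyper(k - 1, K, N - K, M, lower.tail = FALSE)
  p <- pmin(pmax(p, 0), 1)
  data.frame(p = p, q = stats::p.adjust(p, method = method))
}

#' Rank drugs by enrichment significance
#'
#' Sorted by q ascending, then p ascending, then k descending, then drug
#' name (for determinism); the significant flag marks q <= alpha.
#'
#' @param counts data.frame from [count_supporting_models()].
#' @param pq data.frame from [enrichment_pvalues()] (same row order).
#' @param alpha candidate-list threshold on q.
#' @return data.frame: `drug`, `k`, `M`, `p`, `q`, `rank`, `significant`.
#' @export
rank_drugs <- function(counts, pq, alpha = 0.05) {
  tab <- cbind(counts, pq)
  ord <- order(tab$q, tab$p, -tab$k, tab$drug)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$significant <- tab$q <= alpha
  rownames(tab) <- NULL
  tab
}

#' Test candidate overlap with a known-geroprotector set
#'
#' Builds the 2x2 candidate x known contingency table over the screened
#' universe and returns the one-sided (enrichment) Fisher exact p value,
#' with the observed and expected overlap. Matching is case-insensitive
#' and duplicate names are dropped.
#'
#' @param candidates character vector of candidate drugs.
#' @param known character vector of known geroprotectors (must lie in the
#'   universe after matching).
#' @param universe either the full vector of screened drug names or the
#'   universe size (in which case candidates/known are assumed screened).
#' @return list: `p`, `table` (2x2), `overlap`, `expected`.
#' @export
known_set_overlap_test <- function(candidates, known, universe) {
  if (length(universe) == 1L && is.numeric(universe)) {
    n_universe <- as.integer(universe)
    candidates <- unique(tolower(candidates))
    known <- unique(tolower(known))
    overlap <- length(intersect(candidates, known))
    n_cand <- length(candidates)
    n_known <- length(known)
  } else {
    universe <- unique(tolower(universe))
    if (length(universe) == 0L) stop("empty screened universe")
    candidates <- intersect(unique(tolower(candidates)), universe)
    known <- intersect(unique(tolower(known)), universe)
    overlap <- length(intersect(candidates, known))
    n_cand <- length(candidates)
    n_known <- length(known)
    n_universe <- length(universe)
  }
  if (n_universe == 0L) stop("empty screened universe")
  tab <- matrix(c(overlap, n_cand - overlap,
                  n_known - overlap,
                  n_universe - n_cand - n_known + overlap),
                nrow = 2,
                dimnames = list(candidate = c("yes", "no"),
                                known = c("yes", "no")))
  if (any(tab < 0)) stop("inconsistent contingency table")
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p = ft$p.value, table = tab, overlap = overlap,
       expected = n_known * n_cand / n_universe)
}
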