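#' Upper-tail hypergeometric probability for a chimera pair
#'
#' Exact probability that a pair's chimera count is at least as large as
#' observed given the partners' totals: `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)` — population `N` (all interaction reads in
#' the sample), `K` successes (interaction reads involving partner A), `n`
#' draws (interaction reads involving partner B). One-sided by design: only
#' enrichment is biologically meaningful for a ligation assay. The tail is
#' accumulated in log space from log-factorials (via `lchoose`), so it is
#' stable for large counts; the parameterization is symmetric in `(K, n)`.
#'
#' @param k Observed pair count(s).
#' @param K,n Marginal totals of the two partners (each includes `k`).
#' @param N Total interaction count.
#' @return Probability in `[0, 1]`; vectorized over its arguments.
#' @examples
#' hypergeom_pvalue(3, 3, 3, 10) # == 1 / choose(10, 3)
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); N <- rep_len(as.numeric(N), len)
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)))
    stop("require 0 <= k <= min(K, n) and K, n <= N", call. = FALSE)
  vapply(seq_len(len), function(i) {
    lo <- max(0, k[i], K[i] + n[i] - N[i])
    if (k[i] <= max(0, K[i] + n[i] - N[i])) return(1)
    xs <- lo:min(K[i], n[i])
    lp <- lchoose(K[i], xs) + lchoose(N[i] - K[i], n[i] - xs) - lchoose(N[i], n[i])
    min(1, exp(logsumexp(lp)))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts ascending, sets `q_i = p_i * m / i`, enforces monotone
#' non-decreasing values from the largest p down, caps at 1 and restores the
#' input order. Declaring pairs with `q < alpha` significant controls the
#' false discovery rate at `alpha`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Test every interacting pair for chimera enrichment
#'
#' Runs [hypergeom_pvalue()] on each pair of the (replicate-merged)
#' interaction matrix with `K = K_A`, `n = K_B`, `N` = the matrix total, then
#' BH-adjusts across all tested pairs. Self pairs never occur (they are
#' intramolecular by construction).
#'
#' @param matrix An `interaction_matrix`.
#' @param min_count Only pairs with at least this many chimeras are tested
#'   (default 1, i.e. every observed pair).
#' @return An `interaction_results` `data.table`: `featureA`, `featureB`,
#'   `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `significant_raw` (`p_raw <
#'   0.05`), `significant_fdr` (`p_adj < 0.05`), ordered by `(p_raw,
#'   featureA, featureB)`.
#' @export
test_all_pairs <- function(matrix, min_count = 1L) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  pairs <- matrix$pairs[count >= min_count]
  if (!nrow(pairs)) {
    return(data.table(featureA = character(0), featureB = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      significant_raw = logical(0), significant_fdr = logical(0)))
  }
  res <- data.table(
    featureA = pairs$featureA, featureB = pairs$featureB,
    k = pairs$count,
    K = unname(matrix$marginals[pairs$featureA]),
    n = unname(matrix$marginals[pairs$featureB]),
    N = matrix$N
  )
  res[, p_raw := hypergeom_pvalue(k, K, n, N)]
  res[, p_adj := bh_adjust(p_raw)]
  res[, significant_raw := p_raw < 0.05]
  res[, significant_fdr := p_adj < 0.05]
  setorder(res, p_raw, featureA, featureB)
  res[]
}

#' Extract significant interaction sets
#'
#' Two nested sets, as in the original analysis: pairs with raw `p < 0.05`
#' ("significant interactions") and the subset surviving BH-FDR control at
#' `fdr`. Deterministic ordering by `(p_raw, featureA, featureB)`.
#'
#' @param results An `interaction_results` table from [test_all_pairs()].
#' @param raw_alpha Raw p-value threshold (default 0.05).
#' @param fdr FDR threshold on adjusted p-values (default 0.05).
#' @return List with elements `raw` and `fdr` (the latter a subset of the
#'   former, since `p_adj >= p_raw`).
#' @export
extract_significant <- function(results, raw_alpha = 0.05, fdr = 0.05) {
  res <- as.data.table(results)
  setorder(res, p_raw, featureA, featureB)
  list(raw = res[p_raw < raw_alpha],
       fdr = res[p_adj < fdr])
}
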