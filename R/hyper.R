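#' Cumulative hypergeometric upper tail
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked items in `n` draws without replacement from a
#' population of `N` items of which `K` are marked. This is the enrichment
#' statistic shared by the motif-enrichment and over-representation tests;
#' it is evaluated in log space for numerical stability.
#'
#' @param k observed count of marked draws (vectorised).
#' @param K marked items in the population.
#' @param n number of draws.
#' @param N population size.
#' @param log.p return the natural log of the tail probability.
#' @return Numeric vector of upper-tail probabilities (or their natural
#'   logs), `1` (log `0`) when `k <= 0`.
#' @examples
#' hyper_upper_tail(5, K = 6, n = 10, N = 20)  # 13013/184756
#' @export
hyper_upper_tail <- function(k, K, n, N, log.p = FALSE) {
  if (any(N < 0) || any(K < 0) || any(n < 0) || any(K > N) || any(n > N))
    stop_usage("hypergeometric parameters need 0 <= K, n <= N")
  if (any(k > pmin(n, K)))
    stop_usage("k cannot exceed min(n, K)")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE, log.p = log.p)
}

#' Benjamini-Hochberg adjusted hypergeometric over-representation
#'
#' Internal shared helper: given per-row counts, compute upper-tail p in
#' log space plus the linear-scale p (exp of log), then BH-adjust.
#' @noRd
hyper_table <- function(k, K, n, N) {
  log_p <- hyper_upper_tail(k, K, n, N, log.p = TRUE)
  data.frame(k = k, n = n, K = K, N = N,
             p_value = exp(log_p), log_p = log_p)
}
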