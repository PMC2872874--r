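#' Wallenius non-central hypergeometric probability mass function
#'
#' Law of the number of "biased" items obtained when n items are drawn
#' without replacement from an urn of N items — K of them biased with weight
#' `odds`, the remaining N - K with weight 1 — each draw taken with
#' probability proportional to the total remaining weight of its class.
#' At `odds = 1` this is the central hypergeometric distribution.
#'
#' Computed by the exact forward recursion over draws: after j draws with x
#' biased items taken, the next draw is biased with probability
#' odds (K - x) / (odds (K - x) + (N - K) - (j - x)). The recursion costs
#' O(n min(n, K)) and is exact up to floating-point rounding, so no
#' quadrature of the usual integral representation is needed at the problem
#' sizes that arise in category testing.
#'
#' @param N urn size (genes in universe).
#' @param K number of biased items (genes in the category).
#' @param n number of draws (DE genes).
#' @param odds positive weight ratio of biased to unbiased items.
#' @return numeric vector of probabilities for x = 0, 1, ..., min(n, K).
#' @export
wallenius_pmf <- function(N, K, n, odds) {
  if (any(c(N, K, n) != floor(c(N, K, n))) || N < 1 || K < 0 || n < 0) {
    stop_validation("N, K, n must be non-negative integers with N >= 1")
  }
  if (K > N || n > N) stop_validation("require K <= N and n <= N")
  if (!is.finite(odds) || odds <= 0) stop_validation("odds must be positive")
  xmax <- min(n, K)
  cur <- c(1, rep(0, xmax))
  if (n == 0L) return(cur)
  x <- 0:xmax
  for (j in 0:(n - 1L)) {
    wb <- pmax(odds * (K - x), 0)
    wu <- pmax((N - K) - (j - x), 0)
    tot <- wb + wu
    pb <- ifelse(tot > 0, wb / tot, 0)
    nxt <- cur * (1 - pb)
    if (xmax > 0) {
      nxt[-1] <- nxt[-1] + (cur * pb)[-(xmax + 1)]
    }
    cur <- nxt
  }
  cur
}

#' Hypergeometric over/under-representation p-values
#'
#' Tail probabilities of the central hypergeometric distribution for a
#' 2x2 gene-category contingency: `p_over` = P(X >= k), `p_under` =
#' P(X <= k), both including the observed value, for X ~
#' Hypergeometric(N, K, n). This is the classical (biased) null of standard
#' category over-representation analysis.
#'
#' @param N genes in universe.
#' @param K genes in the category.
#' @param n DE genes.
#' @param k DE genes in the category.
#' @return list with `p_over` and `p_under`.
#' @export
hypergeometric_pvalues <- function(N, K, n, k) {
  check_contingency(N, K, n, k)
  list(p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = phyper(k, K, N - K, n))
}

#' Wallenius over/under-representation p-values
#'
#' Tail probabilities of the Wallenius non-central hypergeometric
#' distribution (see [wallenius_pmf()]), the bias-corrected approximation in
#' which every gene inside the category shares the category's mean PWF
#' weight and every gene outside shares the complement's mean. Both tails
#' include the observed value. At `odds = 1` the result equals
#' [hypergeometric_pvalues()] up to floating-point rounding.
#'
#' @inheritParams hypergeometric_pvalues
#' @param odds positive non-centrality parameter, typically from
#'   [category_odds()].
#' @return list with `p_over` and `p_under`.
#' @export
wallenius_pvalues <- function(N, K, n, k, odds) {
  check_contingency(N, K, n, k)
  pmf <- wallenius_pmf(N, K, n, odds)
  p_over <- sum(pmf[(k + 1):length(pmf)])
  p_under <- sum(pmf[1:(k + 1)])
  list(p_over = min(max(p_over, 0), 1), p_under = min(max(p_under, 0), 1))
}

check_contingency <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(vals)) || any(vals != floor(vals)) || any(vals < 0)) {
    stop_validation("contingency counts must be non-negative integers")
  }
  if (K > N || n > N) stop_validation("require K <= N and n <= N")
  if (k > min(K, n)) stop_validation("require k <= min(K, n)")
  if (k < max(0, n - (N - K))) stop_validation("k below the feasible minimum n - (N - K)")
  invisible(TRUE)
}

#' Mean-weight odds ratio of a category
#'
#' The non-centrality parameter of the Wallenius approximation: the mean PWF
#' weight of genes inside the category divided by the mean PWF weight of
#' genes outside it.
#'
#' @param weights_in PWF weights of in-category genes.
#' @param weights_out PWF weights of the remaining genes.
#' @return positive scalar odds.
#' @export
category_odds <- function(weights_in, weights_out) {
  if (!length(weights_in)) stop_validation("category is empty")
  if (!length(weights_out)) stop_validation("category spans the whole universe")
  w <- c(weights_in, weights_out)
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
    stop_validation("weights must lie in (0, 1]")
  }
  mean(weights_in) / mean(weights_out)
}
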