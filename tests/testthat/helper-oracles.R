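# Independent oracles, deliberately naive: they enumerate the sampling
# process path by path instead of using the package's forward recursion.

# Exhaustive enumeration over ordered class sequences (biased/unbiased) of
# n sequential draws without replacement; probability of each path is the
# product of per-draw class probabilities given the remaining weights.
enum_wallenius_pmf <- function(N, K, n, odds) {
  xmax <- min(n, K)
  pmf <- numeric(xmax + 1)
  paths <- expand.grid(rep(list(c(TRUE, FALSE)), n))
  for (r in seq_len(nrow(paths))) {
    path <- as.logical(paths[r, ])
    prob <- 1
    b_left <- K
    u_left <- N - K
    ok <- TRUE
    for (d in seq_len(n)) {
      tw <- odds * b_left + u_left
      if (path[d]) {
        if (b_left == 0) { ok <- FALSE; break }
        prob <- prob * odds * b_left / tw
        b_left <- b_left - 1
      } else {
        if (u_left == 0) { ok <- FALSE; break }
        prob <- prob * u_left / tw
        u_left <- u_left - 1
      }
    }
    if (ok) {
      x <- sum(path)
      pmf[x + 1] <- pmf[x + 1] + prob
    }
  }
  pmf
}

# Item-level enumeration (every ordered sequence of distinct items), the
# most literal reading of the sampling scheme; practical only for N <= 6.
enum_wallenius_pmf_items <- function(N, K, n, odds) {
  w <- c(rep(odds, K), rep(1, N - K))
  pmf <- numeric(min(n, K) + 1)
  recurse <- function(remaining, x, prob, left) {
    if (left == 0) {
      pmf[x + 1] <<- pmf[x + 1] + prob
      return(invisible())
    }
    tw <- sum(w[remaining])
    for (i in remaining) {
      recurse(remaining[remaining != i], x + (i <= K), prob * w[i] / tw,
              left - 1)
    }
  }
  recurse(seq_len(N), 0, 1, n)
  pmf
}
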