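#' Poisson exact test for two count libraries
#'
#' Exact test of equal (library-size-adjusted) Poisson rates for one gene
#' sequenced in two libraries. Conditional on the total s = y1 + y2, y1 is
#' Binomial(s, M1/(M1+M2)) under the null, so the test reduces to an exact
#' binomial test. The two-sided p-value uses the minimum-likelihood rule:
#' the sum of P(j) over all outcomes j whose probability does not exceed
#' that of the observed y1 (the convention of Fisher's exact test). s = 0
#' carries no information and returns 1.
#'
#' All four arguments are recycled to a common length, so whole count
#' tables can be tested in one vectorised call.
#'
#' @param y1,y2 non-negative observed counts.
#' @param M1,M2 positive library sizes.
#' @return two-sided p-value(s) in (0, 1].
#' @export
poisson_exact_pvalue <- function(y1, y2, M1, M2) {
  n <- max(length(y1), length(y2), length(M1), length(M2))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  M1 <- rep_len(M1, n); M2 <- rep_len(M2, n)
  if (any(!is.finite(y1)) || any(!is.finite(y2)) || any(y1 < 0) || any(y2 < 0)) {
    stop_validation("counts must be non-negative")
  }
  if (any(y1 != floor(y1)) || any(y2 != floor(y2))) {
    stop_validation("counts must be integers")
  }
  if (any(!is.finite(M1)) || any(!is.finite(M2)) || any(M1 <= 0) || any(M2 <= 0)) {
    stop_validation("library sizes must be positive")
  }
  p0 <- M1 / (M1 + M2)
  s <- y1 + y2
  vapply(seq_len(n), function(i) .binom_minlik_two_sided(y1[i], s[i], p0[i]), 0)
}

# Two-sided exact binomial p-value, minimum-likelihood rule. Relative
# tolerance (1 + 1e-7) on the probability comparison, as in fisher.test,
# guards against ties lost to rounding. For large s the outcomes MORE
# probable than observed form a contiguous window around the mode, found by
# outward scan; p = 1 - P(window), computed wholly in log space.
.binom_minlik_two_sided <- function(y, s, p0) {
  if (s == 0) return(1)
  reltol <- 1e-7
  lobs <- dbinom(y, s, p0, log = TRUE)
  if (s <= 10000) {
    lp <- dbinom(0:s, s, p0, log = TRUE)
    p <- sum(exp(lp[lp <= lobs + reltol]))
  } else {
    mode <- floor((s + 1) * p0)
    if (dbinom(mode, s, p0, log = TRUE) <= lobs + reltol) return(1)
    lo <- mode
    while (lo > 0 && dbinom(lo - 1, s, p0, log = TRUE) > lobs + reltol) lo <- lo - 1
    hi <- mode
    while (hi < s && dbinom(hi + 1, s, p0, log = TRUE) > lobs + reltol) hi <- hi + 1
    inside <- pbinom(hi, s, p0) - pbinom(lo - 1, s, p0)
    p <- 1 - inside
  }
  min(max(p, dbinom(y, s, p0)), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m p_(j) / j, capped at
#' 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differential expression on a gene table
#'
#' Applies [poisson_exact_pvalue()] per gene with the table's library sizes,
#' adjusts across the whole universe with [bh_adjust()], and flags genes with
#' q-value at or below `fdr_threshold`. The enrichment machinery works with
#' any procedure for identifying DE genes: supply precomputed binary flags
#' via `flags` to bypass the test entirely (p/q columns are then left NA).
#'
#' @param table a `gene_table`.
#' @param fdr_threshold FDR threshold in (0, 1); default 1e-4, the stringent
#'   threshold appropriate for deeply sequenced two-library designs.
#' @param flags optional logical/0-1 vector of externally supplied DE calls,
#'   in table row order.
#' @return the table with columns `de_pvalue`, `de_qvalue`, `de_flag` added.
#' @export
call_de <- function(table, fdr_threshold = 1e-4, flags = NULL) {
  if (!is.null(flags)) {
    if (length(flags) != nrow(table)) {
      stop_validation("flags must have one entry per gene")
    }
    table$de_pvalue <- NA_real_
    table$de_qvalue <- NA_real_
    table$de_flag <- as.logical(flags)
    return(table)
  }
  if (!is.finite(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop_validation("fdr_threshold must lie in (0, 1)")
  }
  ls <- lib_sizes(table)
  if (is.null(ls)) stop_validation("table has no library sizes; use read_gene_table()")
  p <- poisson_exact_pvalue(table$count_1, table$count_2, ls[1], ls[2])
  q <- bh_adjust(p)
  table$de_pvalue <- p
  table$de_qvalue <- q
  table$de_flag <- q <= fdr_threshold
  table
}
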