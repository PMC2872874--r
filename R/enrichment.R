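#' Resampling p-values for one category under the PWF-weighted null
#'
#' Replicates the DE-gene selection under the bias-aware null: each
#' replicate draws `n_de` genes without replacement, each draw taken with
#' probability proportional to the remaining genes' PWF weights — the
#' finite-population sampling scheme whose exact law is Wallenius'
#' non-central hypergeometric distribution. Draws use the equivalent
#' exponential-keys construction (smallest n_de of Exp(1)/w_i), which is
#' O(N) per replicate. p-values use the add-one estimator
#' (b + 1) / (reps + 1), so a reported p of exactly 0 is impossible and
#' `p_over >= 1 / (reps + 1)`.
#'
#' @param weights per-gene PWF weights in (0, 1], whole universe.
#' @param category_members logical vector, same length, marking the
#'   category's genes.
#' @param n_de number of DE genes (draws per replicate), 0 < n_de < N.
#' @param k_observed observed DE genes in the category.
#' @param reps number of replicates (>= 1).
#' @param seed integer seed; identical seed gives identical output.
#' @return list with `p_over`, `p_under`, and `null_counts`, the histogram
#'   of in-category counts over replicates (index x + 1 holds the count of
#'   replicates with x members).
#' @export
sampling_pvalues <- function(weights, category_members, n_de, k_observed,
                             reps = 2000, seed = NULL) {
  N <- length(weights)
  if (length(category_members) != N) {
    stop_validation("weights and category_members must have equal length")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop_validation("all sampling weights must be positive")
  }
  if (n_de <= 0 || n_de >= N) stop_validation("require 0 < n_de < N")
  if (reps < 1) stop_validation("reps must be >= 1")
  category_members <- as.logical(category_members)
  K <- sum(category_members)
  counts <- with_seed(seed, {
    out <- integer(reps)
    for (r in seq_len(reps)) {
      keys <- rexp(N) / weights
      thr <- sort(keys, partial = n_de)[n_de]
      out[r] <- sum(category_members & keys <= thr)
    }
    out
  })
  list(
    p_over = (sum(counts >= k_observed) + 1) / (reps + 1),
    p_under = (sum(counts <= k_observed) + 1) / (reps + 1),
    null_counts = tabulate(counts + 1L, nbins = min(n_de, K) + 1L)
  )
}

# One replicate ensemble scored against every category at once.
# memb: sparse categories x genes 0/1 matrix. Returns exceedance counts
# (over: #reps with count >= k; under: <= k) per category, accumulated in
# chunks so the cats x reps count matrix never materialises in full.
.shared_null_exceedances <- function(weights, memb, n_de, k, reps,
                                     chunk = 2000L) {
  N <- length(weights)
  n_cat <- nrow(memb)
  over <- integer(n_cat)
  under <- integer(n_cat)
  done <- 0L
  while (done < reps) {
    m <- min(chunk, reps - done)
    ii <- integer(n_de * m)
    jj <- integer(n_de * m)
    for (r in seq_len(m)) {
      keys <- rexp(N) / weights
      thr <- sort(keys, partial = n_de)[n_de]
      sel <- which(keys <= thr)[seq_len(n_de)]
      idx <- ((r - 1L) * n_de + 1L):(r * n_de)
      ii[idx] <- sel
      jj[idx] <- r
    }
    D <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, m))
    cnt <- as.matrix(memb %*% D)
    over <- over + rowSums(cnt >= k)
    under <- under + rowSums(cnt <= k)
    done <- done + m
  }
  list(over = over, under = under)
}

#' Test every category for over/under-representation among DE genes
#'
#' The end-to-end enrichment stage. For each category with at least one gene
#' in the universe it computes the 2x2 contingency (N genes, K in category,
#' n DE, k DE in category) and a p-value for over- and under-representation
#' under one of three nulls:
#'
#' * `"hypergeometric"` — the classical Fisher-test null that every gene is
#'   equally likely to be DE; biased for count data.
#' * `"wallenius"` — Wallenius non-central hypergeometric with the
#'   category's mean-PWF odds ratio ([category_odds()]); fast, assumes equal
#'   weights within the category.
#' * `"sampling"` — weighted resampling without replacement using each
#'   gene's own PWF weight; the reference method when it and Wallenius
#'   disagree. A single ensemble of `reps` replicate draws is shared across
#'   all categories, so category p-values come from a common null.
#'
#' Results carry a BH-adjusted `fdr_over` across categories and are ranked
#' by ascending `p_over` with lexicographic tie-break on category id
#' (ranking uses the raw p-value; the FDR column is reported only).
#'
#' @param table a `gene_table` with `de_flag` (from [call_de()]) and, for
#'   the corrected methods, `pwf_weight` (from [evaluate_pwf()], stored by
#'   [run_pipeline()] or by hand).
#' @param categories a `category_map`.
#' @param method `"wallenius"` (default), `"sampling"`, or
#'   `"hypergeometric"`.
#' @param reps sampling replicates (sampling method only); 2,000 by default,
#'   200,000 recommended when fine ranking of the very top categories
#'   matters.
#' @param seed integer seed for the sampling method.
#' @return data.frame with one row per category: `category_id`,
#'   `n_category`, `n_de_in_category`, `odds`, `p_over`, `p_under`,
#'   `fdr_over`, `method`, `rank`; attributes `N`, `n_de`, `method`,
#'   `reps`/`seed` (sampling).
#' @export
test_categories <- function(table, categories,
                            method = c("wallenius", "sampling", "hypergeometric"),
                            reps = 2000, seed = NULL) {
  method <- match.arg(method)
  if (is.null(table$de_flag) || anyNA(table$de_flag)) {
    stop_validation("table lacks DE flags; run call_de() first")
  }
  universe <- intersect(table$gene_id, categories$universe)
  if (!length(universe)) stop_validation("gene table and category map share no genes")
  tab <- table[match(universe, table$gene_id), ]
  N <- length(universe)
  n_de <- sum(tab$de_flag)
  if (n_de < 1) stop_validation("no DE genes in the universe")
  if (n_de >= N) stop_validation("every gene is DE; enrichment is undefined")

  if (method != "hypergeometric") {
    if (is.null(tab$pwf_weight) || anyNA(tab$pwf_weight)) {
      stop_validation("method '%s' needs PWF weights; fit and evaluate a PWF first",
                      method)
    }
    if (any(tab$pwf_weight <= 0)) stop_validation("PWF weights must be positive")
  }

  cat2genes <- lapply(categories$cat2genes, function(g) g[g %in% universe])
  cat2genes <- cat2genes[vapply(cat2genes, length, 1L) > 0L]
  if (!length(cat2genes)) stop_validation("no category has genes in the universe")
  cat_ids <- names(cat2genes)
  n_cat <- length(cat_ids)
  gene_pos <- seq_len(N)
  names(gene_pos) <- tab$gene_id
  K <- vapply(cat2genes, length, 1L)
  de_set <- tab$gene_id[tab$de_flag]
  k <- vapply(cat2genes, function(g) sum(g %in% de_set), 1L)

  if (method == "hypergeometric") {
    odds <- rep(1, n_cat)
    p_over <- phyper(k - 1, K, N - K, n_de, lower.tail = FALSE)
    p_under <- phyper(k, K, N - K, n_de)
  } else {
    w <- tab$pwf_weight
    w_total <- sum(w)
    w_in <- vapply(cat2genes, function(g) sum(w[gene_pos[g]]), 0)
    mean_in <- w_in / K
    mean_out <- (w_total - w_in) / (N - K)
    if (any(N == K)) stop_validation("a category spans the whole universe")
    odds <- mean_in / mean_out
    if (method == "wallenius") {
      p_over <- numeric(n_cat)
      p_under <- numeric(n_cat)
      for (i in seq_len(n_cat)) {
        pv <- wallenius_pvalues(N, K[i], n_de, k[i], odds[i])
        p_over[i] <- pv$p_over
        p_under[i] <- pv$p_under
      }
    } else {
      ii <- unlist(lapply(seq_len(n_cat),
                          function(i) rep.int(i, K[i])), use.names = FALSE)
      jj <- unname(gene_pos[unlist(cat2genes, use.names = FALSE)])
      memb <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n_cat, N))
      exc <- with_seed(seed,
        .shared_null_exceedances(w, memb, n_de, k, reps))
      p_over <- (exc$over + 1) / (reps + 1)
      p_under <- (exc$under + 1) / (reps + 1)
    }
  }

  res <- data.frame(
    category_id = cat_ids,
    n_category = as.integer(K),
    n_de_in_category = as.integer(k),
    odds = odds,
    p_over = p_over,
    p_under = p_under,
    fdr_over = bh_adjust(p_over),
    method = method,
    stringsAsFactors = FALSE
  )
  ord <- order(res$p_over, res$category_id)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "N") <- N
  attr(res, "n_de") <- n_de
  attr(res, "method") <- method
  if (method == "sampling") {
    attr(res, "reps") <- reps
    attr(res, "seed") <- seed
  }
  res
}
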