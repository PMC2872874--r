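#' Per-category gene length bias test
#'
#' For each category, a two-sided Mann-Whitney U (Wilcoxon rank-sum) test
#' comparing the lengths of its genes against the lengths of all other genes
#' in the universe, together with the category's median gene length. An
#' excess of small p-values over categories indicates that category
#' membership is length-structured, i.e. that an uncorrected enrichment
#' analysis will be biased. Categories with fewer than `min_size` genes in
#' or out of the category are skipped with a warning.
#'
#' @param lengths named positive numeric vector of gene lengths (names are
#'   gene ids spanning the universe).
#' @param categories a `category_map`.
#' @param min_size minimum genes on each side of the comparison (default 2).
#' @return data.frame with `category_id`, `n_genes`, `median_length`,
#'   `mwu_pvalue`.
#' @export
category_length_bias_test <- function(lengths, categories, min_size = 2) {
  if (!length(lengths)) stop_validation("empty universe")
  if (is.null(names(lengths))) stop_validation("lengths must be named by gene id")
  ids <- names(categories$cat2genes)
  keep <- logical(length(ids))
  med <- num <- p <- numeric(length(ids))
  n_in <- integer(length(ids))
  for (i in seq_along(ids)) {
    memb <- names(lengths) %in% categories$cat2genes[[ids[i]]]
    if (sum(memb) < min_size || sum(!memb) < min_size) next
    keep[i] <- TRUE
    n_in[i] <- sum(memb)
    med[i] <- median(lengths[memb])
    pv <- suppressWarnings(
      wilcox.test(lengths[memb], lengths[!memb], exact = FALSE)$p.value)
    # fully tied data gives a 0/0 z-statistic: no rank separation, p = 1
    p[i] <- if (is.na(pv)) 1 else pv
  }
  if (any(!keep)) {
    warning(sprintf("skipped %d categor%s with fewer than %d genes in or out",
                    sum(!keep), if (sum(!keep) == 1) "y" else "ies", min_size))
  }
  data.frame(category_id = ids[keep], n_genes = n_in[keep],
             median_length = med[keep], mwu_pvalue = p[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ranked category list from enrichment results
#'
#' @param results data.frame from [test_categories()] (or any data.frame
#'   with `category_id` and `p_over`).
#' @return character vector of category ids, ascending p-value, ties broken
#'   lexicographically.
#' @export
ranked_list <- function(results) {
  results$category_id[order(results$p_over, results$category_id)]
}

#' Top-k discrepancy between two ranked lists
#'
#' The number of categories in the top k of one list absent from the top k
#' of the other; symmetric because both top-k sets have size k.
#'
#' @param a,b character vectors of category ids, most significant first,
#'   over the same category universe.
#' @param k list size to compare.
#' @return integer discrepancy count in `[0, k]`.
#' @export
rank_discrepancy <- function(a, b, k) {
  check_ranked_pair(a, b)
  if (k < 1 || k > length(a) || k > length(b)) {
    stop_validation("k must lie in [1, length of both lists]")
  }
  length(setdiff(a[seq_len(k)], b[seq_len(k)]))
}

#' Per-category rank changes between two methods
#'
#' Tabulates each category's 1-based rank in two lists, the change in rank
#' going from list `a` to list `b` (positive = more significant under `b`),
#' and an optional per-category statistic (for example mean log gene length)
#' for plotting rank change against the bias covariate.
#'
#' @param a,b ranked lists over the same categories.
#' @param category_stats optional named numeric vector (names = category
#'   ids).
#' @return data.frame with `category_id`, `rank_a`, `rank_b`, `delta_rank`
#'   (= rank_a - rank_b) and, if supplied, `stat`.
#' @export
rank_change_table <- function(a, b, category_stats = NULL) {
  check_ranked_pair(a, b)
  out <- data.frame(
    category_id = a,
    rank_a = seq_along(a),
    rank_b = match(a, b),
    stringsAsFactors = FALSE
  )
  out$delta_rank <- out$rank_a - out$rank_b
  if (!is.null(category_stats)) out$stat <- unname(category_stats[a])
  out
}

#' Overlap fraction curve between two ranked lists
#'
#' For each list size k, the fraction of the test list's top k that also
#' appears in the reference list's top k; identically
#' 1 - discrepancy(k) / k.
#'
#' @param reference,test ranked lists over the same categories.
#' @param ks ascending integer vector of list sizes.
#' @return data.frame with `k` and `overlap_fraction`.
#' @export
overlap_fraction_curve <- function(reference, test, ks) {
  check_ranked_pair(reference, test)
  if (is.unsorted(ks)) stop_validation("ks must be sorted ascending")
  frac <- vapply(ks, function(k) {
    1 - rank_discrepancy(test, reference, k) / k
  }, 0)
  data.frame(k = as.integer(ks), overlap_fraction = frac)
}

#' Binomial sign test comparing two methods' category recovery
#'
#' Given per-category indicators of whether each of two methods recovered a
#' reference category, restricts to discordant categories (recovered by
#' exactly one method) and tests whether method `a` recovers more of them
#' than expected under a null in which both methods are equally likely to
#' recover each category — a one-sided exact binomial test of
#' #(a only) against Binomial(n_discordant, 1/2). With no discordant
#' categories the p-value is 1.
#'
#' @param recovered_a,recovered_b logical vectors over the same categories.
#' @return one-sided p-value (a better than b).
#' @export
method_comparison_binomial <- function(recovered_a, recovered_b) {
  if (length(recovered_a) != length(recovered_b)) {
    stop_validation("recovery vectors must have equal length")
  }
  a <- as.logical(recovered_a)
  b <- as.logical(recovered_b)
  disc <- xor(a, b)
  n_disc <- sum(disc)
  if (n_disc == 0) return(1)
  a_only <- sum(a & disc)
  pbinom(a_only - 1, n_disc, 0.5, lower.tail = FALSE)
}

check_ranked_pair <- function(a, b) {
  if (anyDuplicated(a) || anyDuplicated(b)) {
    stop_validation("ranked lists must not contain duplicates")
  }
  if (length(a) != length(b) || !setequal(a, b)) {
    stop_validation("ranked lists must cover the same categories")
  }
  invisible(TRUE)
}
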