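test_that("sampling with uniform weights agrees with the hypergeometric", {
  N <- 50; K <- 10; n_de <- 10; k <- 5; reps <- 20000
  members <- c(rep(TRUE, K), rep(FALSE, N - K))
  pv <- sampling_pvalues(rep(0.5, N), members, n_de, k, reps = reps, seed = 17)
  target <- phyper(k - 1, K, N - K, n_de, lower.tail = FALSE)
  se <- sqrt(target * (1 - target) / reps)
  expect_lt(abs(pv$p_over - target), 3 * se)
  expect_equal(sum(pv$null_counts), reps)
})

test_that("sampling p-values are seeded, floored and validated", {
  members <- c(rep(TRUE, 5), rep(FALSE, 45))
  w <- runif(50, 0.1, 0.9)
  a <- sampling_pvalues(w, members, 10, 2, reps = 500, seed = 123)
  b <- sampling_pvalues(w, members, 10, 2, reps = 500, seed = 123)
  expect_identical(a, b)
  # unattainable k hits the (b+1)/(m+1) floor
  f <- sampling_pvalues(w, members, 10, 6, reps = 200, seed = 1)
  expect_equal(f$p_over, 1 / 201)
  expect_error(sampling_pvalues(c(0, w[-1]), members, 10, 2, reps = 10),
               "positive")
  expect_error(sampling_pvalues(w, members, 50, 2, reps = 10), "n_de < N")
})

test_that("equal weights make wallenius equal hypergeometric end to end", {
  u <- flat_universe()
  rw <- test_categories(u$table, u$map, method = "wallenius")
  rh <- test_categories(u$table, u$map, method = "hypergeometric")
  m <- match(rw$category_id, rh$category_id)
  expect_lt(max(abs(rw$p_over - rh$p_over[m])), 1e-9)
  expect_lt(max(abs(rw$p_under - rh$p_under[m])), 1e-9)
  expect_true(all(rw$odds == 1))
})

test_that("test_categories output contract holds", {
  u <- flat_universe()
  res <- test_categories(u$table, u$map, method = "sampling", reps = 300,
                         seed = 5)
  expect_equal(nrow(res), length(u$map$cat2genes))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(!is.unsorted(res$p_over))
  expect_true(all(res$p_over >= 1 / 301))
  expect_equal(res$fdr_over, bh_adjust(res$p_over))
  # determinism of the shared ensemble
  res2 <- test_categories(u$table, u$map, method = "sampling", reps = 300,
                          seed = 5)
  expect_identical(res$p_over, res2$p_over)
  # corrected methods demand weights
  tab <- u$table
  tab$pwf_weight <- NULL
  expect_error(test_categories(tab, u$map, method = "wallenius"),
               "PWF weights")
  tab2 <- u$table
  tab2$de_flag <- NULL
  expect_error(test_categories(tab2, u$map), "DE flags")
})

test_that("a planted enriched category ranks first under all methods", {
  cfg <- simulation_config(n_genes = 1500, n_categories = 30,
                           category_size_range = c(30, 60),
                           lib_sizes = c(3e5, 3e5), de_fraction = 0.1,
                           fold_change = 6, length_bias_strength = 0.3,
                           enriched_categories = c(cat0001 = 10), seed = 77)
  sim <- simulate_dataset(cfg)
  tab <- call_de(sim$table)
  pwf <- fit_pwf(tab$length_bp, tab$de_flag)
  tab$pwf_weight <- evaluate_pwf(pwf, tab$length_bp)
  for (method in c("hypergeometric", "wallenius", "sampling")) {
    res <- test_categories(tab, sim$map, method = method, reps = 2000,
                           seed = 3)
    expect_equal(res$category_id[1], "cat0001")
  }
})

test_that("sampling and wallenius top lists agree on moderate-range PWFs", {
  cfg <- simulation_config(n_genes = 3000, n_categories = 100,
                           length_bias_strength = 0.3,
                           lib_sizes = c(6e5, 6e5), seed = 13)
  sim <- simulate_dataset(cfg)
  tab <- call_de(sim$table)
  pwf <- fit_pwf(tab$length_bp, tab$de_flag)
  tab$pwf_weight <- evaluate_pwf(pwf, tab$length_bp)
  rw <- test_categories(tab, sim$map, "wallenius")
  rs <- test_categories(tab, sim$map, "sampling", reps = 10000, seed = 19)
  expect_lte(rank_discrepancy(ranked_list(rw), ranked_list(rs), 10), 2)
})
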