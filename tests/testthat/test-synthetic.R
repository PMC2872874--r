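test_that("generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 500, n_categories = 20, seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$map$cat2genes, s2$map$cat2genes)
  expect_identical(s1$truth, s2$truth)
  # different seed, different data
  s3 <- simulate_dataset(simulation_config(n_genes = 500, n_categories = 20,
                                           seed = 43))
  expect_false(identical(s1$table$count_1, s3$table$count_1))
})

test_that("gene-level marginals match their stated distributions", {
  cfg <- simulation_config(n_genes = 10000, seed = 8)
  genes <- generate_genes(cfg)
  # log-normal median within 5% of exp(meanlog)
  expect_lt(abs(median(genes$lengths) - exp(7.8)) / exp(7.8), 0.05)
  expect_equal(sum(genes$true_de), 1000)
  # de_fraction = 0 plants nothing
  g0 <- generate_genes(simulation_config(n_genes = 1000, de_fraction = 0,
                                         seed = 8))
  expect_false(any(g0$true_de))
  expect_true(all(g0$fold == 1))
})

test_that("counts concentrate on configured library sizes", {
  cfg <- simulation_config(n_genes = 5000, lib_sizes = c(1e6, 5e5), seed = 9)
  genes <- generate_genes(cfg)
  tab <- generate_counts(genes, cfg)
  expect_lt(abs(sum(tab$count_1) - 1e6), 3 * sqrt(1e6))
  expect_lt(abs(sum(tab$count_2) - 5e5), 3 * sqrt(5e5))
  # zero expression means zero counts in both conditions
  genes$expressions[1] <- 0
  tab2 <- generate_counts(genes, cfg)
  expect_equal(tab2$count_1[1] + tab2$count_2[1], 0)
})

test_that("length-biased categories skew long; unbiased ones do not", {
  cfg <- simulation_config(n_genes = 2000, n_categories = 40,
                           category_size_range = c(40, 60),
                           length_bias_strength = 0.5,
                           length_bias_direction = "long", seed = 10)
  genes <- generate_genes(cfg)
  cm <- generate_category_map(genes$lengths, cfg, gene_ids = genes$gene_id)
  med_all <- median(genes$lengths)
  meds <- vapply(cm$map$cat2genes, function(g) {
    median(genes$lengths[match(g, genes$gene_id)])
  }, 0)
  biased <- cm$truth$length_biased[match(names(meds), cm$truth$category_id)]
  expect_true(all(meds[biased] > med_all))
  # length-biased membership produces small MWU p-values, unbiased does not
  lens <- genes$lengths
  names(lens) <- genes$gene_id
  bias_res <- category_length_bias_test(lens, cm$map)
  p <- bias_res$mwu_pvalue[match(cm$truth$category_id, bias_res$category_id)]
  expect_lt(median(p[cm$truth$length_biased]), 1e-6)
  expect_gt(median(p[!cm$truth$length_biased]), 0.05)
})

test_that("enriched categories require DE truth and over-sample DE genes", {
  cfg <- simulation_config(n_genes = 2000, n_categories = 10,
                           category_size_range = c(80, 100),
                           enriched_categories = c(cat0001 = 10), seed = 11)
  genes <- generate_genes(cfg)
  expect_error(generate_category_map(genes$lengths, cfg), "true DE")
  cm <- generate_category_map(genes$lengths, cfg, true_de = genes$true_de,
                              gene_ids = genes$gene_id)
  de_frac_in <- function(id) {
    mean(genes$true_de[match(cm$map$cat2genes[[id]], genes$gene_id)])
  }
  expect_gt(de_frac_in("cat0001"), 2 * mean(genes$true_de))
  expect_true(cm$truth$enriched[cm$truth$category_id == "cat0001"])
})

test_that("the generator reproduces the rising DE-proportion trend", {
  cfg <- simulation_config(n_genes = 4000, lib_sizes = c(4e5, 4e5),
                           de_fraction = 0.2, fold_change = 3,
                           n_categories = 10, seed = 12)
  sim <- simulate_dataset(cfg)
  tab <- call_de(sim$table)
  bins <- bin_de_proportions(tab$length_bp, tab$de_flag, bin_size = 400)
  # monotone association between bin median length and DE proportion
  expect_gt(cor(bins$median_covariate, bins$de_proportion,
                method = "spearman"), 0.7)
})

test_that("write_simulation emits files the readers accept", {
  cfg <- simulation_config(n_genes = 300, n_categories = 10, seed = 13)
  sim <- simulate_dataset(cfg)
  prefix <- tempfile()
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))
  tab <- read_gene_table(paths[1], paths[2])
  expect_equal(nrow(tab), 300)
  expect_equal(tab$count_1[match(sim$table$gene_id, tab$gene_id)],
               sim$table$count_1)
  map <- read_category_map(paths[3], "tsv2col", tab$gene_id)
  expect_identical(lapply(map$cat2genes, sort),
                   lapply(sim$map$cat2genes, sort))
})

test_that("configuration validation catches impossible worlds", {
  expect_error(simulation_config(n_genes = 5), "at least 10")
  expect_error(simulation_config(category_size_range = c(50, 20)), "invalid")
  expect_error(simulation_config(n_genes = 100,
                                 category_size_range = c(10, 200)),
               "exceeds")
  expect_error(simulation_config(de_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(fold_change = 0), "positive")
})
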