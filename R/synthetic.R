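#' Simulation configuration
#'
#' Fixes every parameter of the synthetic-data generator. Defaults describe
#' a realistic two-library bulk RNA-seq experiment: 10,000 genes with
#' log-normal transcript lengths (median ~2.4 kb, matching typical human
#' transcripts), gamma-distributed expression, two libraries of two million
#' reads, 10% of genes truly DE at a 4-fold change (direction random per
#' gene), and 500 categories of 10-100 genes. Expected read counts are
#' proportional to expression times transcript length, which is precisely
#' what creates length-dependent power to detect DE.
#'
#' `length_bias_strength` is the probability that a category's members are
#' drawn with length-rank weighting (weight proportional to
#' rank^`length_bias_exponent`, producing a long-gene category, or the
#' reverse rank for a short-gene category per `length_bias_direction`)
#' rather than uniformly. `enriched_categories` is a named numeric vector
#' mapping category ids (e.g. `"cat0007"`) to the odds by which truly-DE
#' genes are over-weighted when that category's members are drawn —
#' genuine enrichment beyond bias expectation.
#'
#' @param n_genes number of genes.
#' @param length_meanlog,length_sdlog log-normal transcript length
#'   parameters (natural log; defaults give median exp(7.8) ~ 2,440 bp).
#' @param expr_shape,expr_rate gamma parameters for expression levels.
#' @param lib_sizes two library sizes (total reads).
#' @param de_fraction fraction of genes truly DE.
#' @param fold_change expression fold change applied to DE genes in
#'   condition 2 (randomly up or down per gene).
#' @param n_categories number of categories.
#' @param category_size_range inclusive integer range of category sizes.
#' @param length_bias_strength probability a category is length-biased.
#' @param length_bias_exponent rank-weight exponent for biased categories.
#' @param length_bias_direction `"both"` (random per category), `"long"`,
#'   or `"short"`.
#' @param enriched_categories named numeric vector of enrichment odds.
#' @param overdispersion negative-binomial overdispersion (1/size); 0 gives
#'   pure Poisson counts, the default matching the Poisson exact DE test.
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 10000,
                              length_meanlog = 7.8, length_sdlog = 0.7,
                              expr_shape = 1.2, expr_rate = 1,
                              lib_sizes = c(2e6, 2e6),
                              de_fraction = 0.1, fold_change = 4,
                              n_categories = 500,
                              category_size_range = c(10, 100),
                              length_bias_strength = 0,
                              length_bias_exponent = 4,
                              length_bias_direction = c("both", "long", "short"),
                              enriched_categories = numeric(0),
                              overdispersion = 0,
                              seed = 1) {
  length_bias_direction <- match.arg(length_bias_direction)
  cfg <- list(n_genes = as.integer(n_genes),
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              expr_shape = expr_shape, expr_rate = expr_rate,
              lib_sizes = as.numeric(lib_sizes),
              de_fraction = de_fraction, fold_change = fold_change,
              n_categories = as.integer(n_categories),
              category_size_range = as.integer(category_size_range),
              length_bias_strength = length_bias_strength,
              length_bias_exponent = length_bias_exponent,
              length_bias_direction = length_bias_direction,
              enriched_categories = enriched_categories,
              overdispersion = overdispersion,
              seed = as.integer(seed))
  if (cfg$n_genes < 10) stop_validation("n_genes must be at least 10")
  if (cfg$length_sdlog < 0 || cfg$expr_shape <= 0 || cfg$expr_rate <= 0) {
    stop_validation("distribution parameters must be positive")
  }
  if (length(cfg$lib_sizes) != 2 || any(cfg$lib_sizes <= 0)) {
    stop_validation("lib_sizes must be two positive numbers")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1 ||
      cfg$length_bias_strength < 0 || cfg$length_bias_strength > 1) {
    stop_validation("fractions must lie in [0, 1]")
  }
  if (cfg$fold_change <= 0) stop_validation("fold_change must be positive")
  if (cfg$category_size_range[1] < 1 ||
      cfg$category_size_range[2] < cfg$category_size_range[1]) {
    stop_validation("invalid category_size_range")
  }
  if (cfg$category_size_range[2] > cfg$n_genes) {
    stop_validation("category size exceeds n_genes")
  }
  if (cfg$overdispersion < 0) stop_validation("overdispersion must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate gene-level truth: lengths, expressions, DE status
#'
#' Lengths are log-normal, expressions gamma; a `de_fraction` of genes is
#' marked truly DE, each with the configured fold change applied in
#' condition 2 (direction up or down with probability 1/2). Seeded from
#' `config$seed`; identical config gives identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `gene_id`, `lengths`, `expressions`, `true_de`
#'   (logical), `fold` (per-gene multiplier applied in condition 2).
#' @export
generate_genes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    lengths <- rlnorm(n, config$length_meanlog, config$length_sdlog)
    expressions <- rgamma(n, shape = config$expr_shape, rate = config$expr_rate)
    n_de <- round(config$de_fraction * n)
    true_de <- logical(n)
    true_de[sample.int(n, n_de)] <- TRUE
    fold <- rep(1, n)
    up <- runif(n) < 0.5
    fold[true_de & up] <- config$fold_change
    fold[true_de & !up] <- 1 / config$fold_change
    list(gene_id = gene_id, lengths = lengths, expressions = expressions,
         true_de = true_de, fold = fold)
  })
}

#' Generate a two-condition count table
#'
#' Expected read count is proportional to expression times transcript
#' length, scaled so each condition's expectations sum to its library size;
#' counts are Poisson (or negative binomial when
#' `config$overdispersion > 0`). DE genes have expression multiplied by
#' their fold factor in condition 2. Seeded from `config$seed + 1`.
#'
#' @param genes output of [generate_genes()].
#' @param config a [simulation_config()].
#' @return a `gene_table` with true DE truth in column `true_de`.
#' @export
generate_counts <- function(genes, config) {
  stopifnot(inherits(config, "simulation_config"))
  le1 <- genes$lengths * genes$expressions
  le2 <- genes$lengths * genes$expressions * genes$fold
  if (sum(le1) <= 0 || sum(le2) <= 0) {
    stop_validation("all expected counts are zero")
  }
  mu1 <- config$lib_sizes[1] * le1 / sum(le1)
  mu2 <- config$lib_sizes[2] * le2 / sum(le2)
  with_seed(config$seed + 1L, {
    if (config$overdispersion > 0) {
      size <- 1 / config$overdispersion
      c1 <- stats::rnbinom(length(mu1), mu = mu1, size = size)
      c2 <- stats::rnbinom(length(mu2), mu = mu2, size = size)
    } else {
      c1 <- rpois(length(mu1), mu1)
      c2 <- rpois(length(mu2), mu2)
    }
    tab <- data.frame(gene_id = genes$gene_id, length_bp = genes$lengths,
                      count_1 = c1, count_2 = c2,
                      true_de = genes$true_de, stringsAsFactors = FALSE)
    as_gene_table(tab, config$lib_sizes)
  })
}

#' Generate a category map with controlled length bias and enrichment
#'
#' Each category draws its members without replacement: uniformly, or (with
#' probability `length_bias_strength`) weighted by length rank raised to
#' `length_bias_exponent` — ascending rank for a long-gene category,
#' descending for a short-gene one. Categories named in
#' `config$enriched_categories` additionally multiply the weight of truly
#' DE genes by the configured odds, planting genuine enrichment beyond what
#' the length structure alone produces. Seeded from `config$seed + 2`.
#'
#' @param lengths per-gene lengths (universe order).
#' @param config a [simulation_config()].
#' @param true_de optional logical truth vector, required when
#'   `config$enriched_categories` is non-empty.
#' @param gene_ids optional gene ids (default `g00001`, ...).
#' @return list with `map` (a `category_map`) and `truth`, a data.frame
#'   with `category_id`, `size`, `length_biased`, `bias_direction`,
#'   `enriched`, `enrichment_odds`.
#' @export
generate_category_map <- function(lengths, config, true_de = NULL,
                                  gene_ids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(lengths)
  if (config$category_size_range[2] > n) {
    stop_validation("category size exceeds number of genes")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(n))
  enr <- config$enriched_categories
  if (length(enr) && is.null(true_de)) {
    stop_validation("enriched categories need the true DE flags")
  }
  with_seed(config$seed + 2L, {
    ids <- sprintf("cat%04d", seq_len(config$n_categories))
    sizes <- sample(seq(config$category_size_range[1],
                        config$category_size_range[2]),
                    config$n_categories, replace = TRUE)
    biased <- runif(config$n_categories) < config$length_bias_strength
    dir <- rep("none", config$n_categories)
    dir[biased] <- switch(config$length_bias_direction,
                          both = sample(c("long", "short"), sum(biased),
                                        replace = TRUE),
                          long = "long", short = "short")
    rk <- rank(lengths, ties.method = "first")
    g_all <- character(0)
    c_all <- character(0)
    for (i in seq_len(config$n_categories)) {
      w <- rep(1, n)
      if (dir[i] == "long") w <- (rk / n)^config$length_bias_exponent
      if (dir[i] == "short") w <- ((n + 1 - rk) / n)^config$length_bias_exponent
      if (ids[i] %in% names(enr)) w <- w * ifelse(true_de, enr[[ids[i]]], 1)
      memb <- sample.int(n, sizes[i], prob = w)
      g_all <- c(g_all, gene_ids[memb])
      c_all <- c(c_all, rep(ids[i], sizes[i]))
    }
    truth <- data.frame(
      category_id = ids, size = sizes, length_biased = biased,
      bias_direction = dir,
      enriched = ids %in% names(enr),
      enrichment_odds = ifelse(ids %in% names(enr),
                               unname(enr[ids]), 1),
      stringsAsFactors = FALSE)
    list(map = category_map(g_all, c_all, gene_ids), truth = truth)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_genes()], [generate_counts()] and
#' [generate_category_map()].
#'
#' @param config a [simulation_config()].
#' @return list with `table` (a `gene_table` including `true_de`), `map`
#'   (a `category_map`), `truth` (category truth table), and `genes` (the
#'   gene-level truth).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  genes <- generate_genes(config)
  table <- generate_counts(genes, config)
  cm <- generate_category_map(genes$lengths, config, true_de = genes$true_de,
                              gene_ids = genes$gene_id)
  list(table = table, map = cm$map, truth = cm$truth, genes = genes)
}

#' Write a simulated dataset to TSV files
#'
#' Writes `<prefix>_counts.tsv`, `<prefix>_lengths.tsv`,
#' `<prefix>_categories.tsv` (two-column associations) and
#' `<prefix>_truth.tsv`, the on-disk formats consumed by
#' [read_gene_table()] and [read_category_map()].
#'
#' @param sim output of [simulate_dataset()].
#' @param prefix output path prefix.
#' @return invisibly, the four file paths.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- paste0(prefix, c("_counts.tsv", "_lengths.tsv",
                            "_categories.tsv", "_truth.tsv"))
  tab <- sim$table
  write.table(data.frame(gene_id = tab$gene_id, count_1 = tab$count_1,
                         count_2 = tab$count_2),
              paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = tab$gene_id,
                         length_bp = format(tab$length_bp, digits = 15,
                                            trim = TRUE)),
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  assoc <- data.frame(
    gene_id = unlist(sim$map$cat2genes, use.names = FALSE),
    category_id = rep(names(sim$map$cat2genes),
                      vapply(sim$map$cat2genes, length, 1L)))
  write.table(assoc, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
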