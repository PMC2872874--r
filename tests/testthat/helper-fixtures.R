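# Small on-disk fixtures, built in code at test time.

write_counts_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_counts <- function(ids = c("g1", "g2", "g3"),
                        c1 = c(10, 0, 5), c2 = c(2, 1, 5)) {
  data.frame(gene_id = ids, count_1 = c1, count_2 = c2)
}

tiny_lengths <- function(ids = c("g1", "g2", "g3"),
                         len = c(500, 1500, 3000)) {
  data.frame(gene_id = ids, length_bp = len)
}

tiny_gene_table <- function(...) {
  read_gene_table(write_counts_file(tiny_counts(...)),
                  write_counts_file(tiny_lengths()))
}

# A gene table + category map with DE flags and constant PWF weights,
# for enrichment-machinery tests that need a ready universe.
flat_universe <- function(n = 300, n_cat = 20, cat_size = 30,
                          n_de = 40, weight = 0.3, seed = 99) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n))
  tab <- data.frame(gene_id = ids,
                    length_bp = exp(stats::rlnorm(n, 1, 0.1)) * 100,
                    count_1 = stats::rpois(n, 50),
                    count_2 = stats::rpois(n, 50),
                    stringsAsFactors = FALSE)
  attr(tab, "lib_sizes") <- c(sum(tab$count_1), sum(tab$count_2))
  class(tab) <- c("gene_table", "data.frame")
  tab$de_flag <- FALSE
  tab$de_flag[sample.int(n, n_de)] <- TRUE
  tab$pwf_weight <- rep(weight, n)
  genes <- unlist(lapply(seq_len(n_cat),
                         function(i) sample(ids, cat_size)))
  cats <- rep(sprintf("cat%03d", seq_len(n_cat)), each = cat_size)
  list(table = tab, map = category_map(genes, cats, ids))
}
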