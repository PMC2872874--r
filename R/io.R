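#' Read per-gene counts and lengths into a gene table
#'
#' Assembles the per-gene table shared by all downstream stages from a counts
#' file and a lengths file. The counts file is a TSV with a header row and
#' three columns: gene id, count in condition 1, count in condition 2. The
#' lengths file is a TSV with a header row and two columns: gene id, length
#' in bp. Gzip-compressed files are accepted (by extension, handled by R's
#' connection machinery).
#'
#' The returned table is restricted to genes present in both files; the
#' number of genes dropped from either side is reported via `message()`.
#' Genes with zero counts in both conditions are retained by default — they
#' can never be called DE, so they correctly dilute category weights — unless
#' `drop_zeros = TRUE`.
#'
#' @param counts_path path to the counts TSV.
#' @param lengths_path path to the lengths TSV.
#' @param lib_sizes optional numeric vector of two library sizes; defaults to
#'   the column sums of the counts table.
#' @param drop_zeros drop genes with zero counts in both conditions.
#' @return A `gene_table`: a data.frame with columns `gene_id`, `length_bp`,
#'   `count_1`, `count_2` and attribute `lib_sizes`. DE and PWF columns
#'   (`de_pvalue`, `de_qvalue`, `de_flag`, `pwf_weight`) are added by later
#'   stages.
#' @export
read_gene_table <- function(counts_path, lengths_path, lib_sizes = NULL,
                            drop_zeros = FALSE) {
  counts <- read.delim(counts_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(counts) < 3L) {
    stop_validation("counts file must have columns: gene_id, count_1, count_2 (got %d columns)",
                    ncol(counts))
  }
  counts <- counts[, 1:3]
  names(counts) <- c("gene_id", "count_1", "count_2")
  lengths <- read.delim(lengths_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(lengths) < 2L) {
    stop_validation("lengths file must have columns: gene_id, length_bp (got %d columns)",
                    ncol(lengths))
  }
  lengths <- lengths[, 1:2]
  names(lengths) <- c("gene_id", "length_bp")

  counts$gene_id <- as.character(counts$gene_id)
  lengths$gene_id <- as.character(lengths$gene_id)
  if (anyDuplicated(counts$gene_id)) {
    stop_validation("duplicate gene_id in counts file: %s",
                    counts$gene_id[anyDuplicated(counts$gene_id)])
  }
  if (anyDuplicated(lengths$gene_id)) {
    stop_validation("duplicate gene_id in lengths file: %s",
                    lengths$gene_id[anyDuplicated(lengths$gene_id)])
  }

  bad <- which(!is.finite(counts$count_1) | !is.finite(counts$count_2) |
                 counts$count_1 < 0 | counts$count_2 < 0)
  if (length(bad)) {
    stop_validation("negative or non-numeric count for gene %s", counts$gene_id[bad[1]])
  }
  bad <- which(!is.finite(lengths$length_bp) | lengths$length_bp <= 0)
  if (length(bad)) {
    stop_validation("non-positive length for gene %s", lengths$gene_id[bad[1]])
  }

  shared <- intersect(counts$gene_id, lengths$gene_id)
  if (!length(shared)) stop_validation("no genes shared between counts and lengths files")
  n_drop_counts <- nrow(counts) - length(shared)
  n_drop_lengths <- nrow(lengths) - length(shared)
  if (n_drop_counts || n_drop_lengths) {
    message(sprintf("read_gene_table: dropped %d gene(s) lacking a length, %d lacking counts",
                    n_drop_counts, n_drop_lengths))
  }

  tab <- merge(counts, lengths, by = "gene_id", sort = TRUE)
  tab <- tab[, c("gene_id", "length_bp", "count_1", "count_2")]

  if (is.null(lib_sizes)) {
    lib_sizes <- c(sum(tab$count_1), sum(tab$count_2))
  }
  if (length(lib_sizes) != 2L || any(!is.finite(lib_sizes)) || any(lib_sizes <= 0)) {
    stop_validation("lib_sizes must be two positive numbers")
  }
  if (any(tab$count_1 > lib_sizes[1]) || any(tab$count_2 > lib_sizes[2])) {
    stop_validation("a gene's count exceeds its library size")
  }
  if (drop_zeros) {
    keep <- tab$count_1 + tab$count_2 > 0
    if (any(!keep)) message(sprintf("read_gene_table: dropped %d all-zero gene(s)", sum(!keep)))
    tab <- tab[keep, , drop = FALSE]
  }
  rownames(tab) <- NULL
  as_gene_table(tab, lib_sizes)
}

as_gene_table <- function(df, lib_sizes) {
  attr(df, "lib_sizes") <- as.numeric(lib_sizes)
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Library sizes of a gene table
#' @param table a `gene_table`.
#' @return numeric vector of length two.
#' @export
lib_sizes <- function(table) attr(table, "lib_sizes")

#' Read a gene-to-category association map
#'
#' Two formats are supported. `tsv2col`: two tab-separated columns, gene id
#' then category id, no header required (a header line is harmless: it simply
#' becomes an association whose gene is not in the universe). `gaf`: GAF 2.x
#' gene association format; gene ids are taken from column 2, category ids
#' from column 5, comment lines starting with `!` are skipped.
#'
#' The map is restricted to `universe`: associations for genes outside the
#' universe are dropped, categories left empty are removed, and duplicate
#' (gene, category) pairs are collapsed.
#'
#' @param path path to the association file (gzip accepted).
#' @param format `"tsv2col"` or `"gaf"`.
#' @param universe character vector of gene ids defining the testable
#'   universe (typically `gene_table$gene_id`).
#' @return A `category_map`: list with `cat2genes` (named list of character
#'   vectors), `gene2cats` (the inverse), and `universe`.
#' @export
read_category_map <- function(path, format = c("tsv2col", "gaf"), universe) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[vapply(parts, length, 1L) >= 5L]
    genes <- vapply(parts, `[[`, "", 2L)
    cats <- vapply(parts, `[[`, "", 5L)
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[vapply(parts, length, 1L) >= 2L]
    genes <- vapply(parts, `[[`, "", 1L)
    cats <- vapply(parts, `[[`, "", 2L)
  }
  if (!length(genes)) stop_validation("no parseable associations in %s", path)
  category_map(genes, cats, universe)
}

#' Construct a category map from association pairs
#'
#' @param genes,categories equal-length character vectors of association
#'   pairs.
#' @param universe gene ids to restrict to.
#' @return A `category_map` (see [read_category_map()]).
#' @export
category_map <- function(genes, categories, universe) {
  universe <- unique(as.character(universe))
  genes <- as.character(genes)
  categories <- as.character(categories)
  if (length(genes) != length(categories)) {
    stop_validation("genes and categories must have equal length")
  }
  keep <- genes %in% universe
  genes <- genes[keep]
  categories <- categories[keep]
  pair <- !duplicated(paste0(genes, "\r", categories))
  genes <- genes[pair]
  categories <- categories[pair]
  if (!length(genes)) stop_validation("no associations left after restriction to universe")
  cat2genes <- split(genes, categories)
  gene2cats <- split(categories, genes)
  structure(list(cat2genes = cat2genes, gene2cats = gene2cats,
                 universe = universe),
            class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat(sprintf("category_map: %d categories, %d annotated genes, universe of %d\n",
              length(x$cat2genes), length(x$gene2cats), length(x$universe)))
  invisible(x)
}

#' Restrict a gene table to annotated genes
#'
#' Standard practice keeps only genes carrying at least one category
#' annotation in the enrichment universe; this changes N and hence every
#' p-value, so the choice is explicit and logged.
#'
#' @param table a `gene_table`.
#' @param map a `category_map`.
#' @param keep_unannotated keep genes without any category.
#' @return the restricted `gene_table`.
#' @export
restrict_to_annotated <- function(table, map, keep_unannotated = FALSE) {
  if (keep_unannotated) return(table)
  keep <- table$gene_id %in% names(map$gene2cats)
  if (any(!keep)) {
    message(sprintf("restrict_to_annotated: dropped %d unannotated gene(s); N = %d",
                    sum(!keep), sum(keep)))
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_gene_table(out, lib_sizes(table))
}

#' Write enrichment results to TSV
#'
#' Rows are sorted by ascending `p_over` with a deterministic lexicographic
#' tie-break on `category_id`. Numeric columns are written with 15
#' significant digits so a round-trip read reproduces values to at least 12
#' significant digits. Lines in `header` are prepended as `#` comments.
#'
#' @param results data.frame from [test_categories()].
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`).
#' @export
write_enrichment_results <- function(results, path, header = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop_validation("results must be a non-empty data.frame")
  }
  cols <- c("category_id", "n_category", "n_de_in_category", "odds",
            "p_over", "p_under", "fdr_over", "method")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) {
    stop_validation("results lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- results[order(results$p_over, results$category_id), cols]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) format(v, digits = 15, trim = TRUE,
                                                  scientific = NA))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read back an enrichment results TSV
#' @param path path written by [write_enrichment_results()].
#' @return data.frame with the written columns.
#' @export
read_enrichment_results <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE,
             colClasses = c(category_id = "character"))
}
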