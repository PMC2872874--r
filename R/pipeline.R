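#' Run configuration for the end-to-end pipeline
#'
#' @param counts,lengths,categories input file paths (see
#'   [read_gene_table()] and [read_category_map()]).
#' @param format category file format, `"tsv2col"` or `"gaf"`.
#' @param covariate bias covariate: `"length"` or `"total_count"`.
#' @param fdr DE FDR threshold (default 1e-4).
#' @param method enrichment null: `"wallenius"`, `"sampling"`, or
#'   `"hypergeometric"`.
#' @param reps sampling replicates.
#' @param seed integer seed recorded in all output headers.
#' @param outdir output directory (created if absent).
#' @param knots PWF spline knots.
#' @param drop_zeros drop all-zero genes from the universe.
#' @param keep_unannotated keep genes without categories in the universe.
#' @param lib_sizes optional two library sizes (default: column sums).
#' @return a validated `run_config` list.
#' @export
run_config <- function(counts, lengths, categories, format = "tsv2col",
                       covariate = c("length", "total_count"),
                       fdr = 1e-4,
                       method = c("wallenius", "sampling", "hypergeometric"),
                       reps = 2000, seed = 1, outdir = ".",
                       knots = 6, drop_zeros = FALSE,
                       keep_unannotated = FALSE, lib_sizes = NULL) {
  covariate <- match.arg(covariate)
  method <- match.arg(method)
  for (p in c(counts, lengths, categories)) {
    if (!file.exists(p)) stop_validation("input file does not exist: %s", p)
  }
  structure(list(counts = counts, lengths = lengths, categories = categories,
                 format = format, covariate = covariate, fdr = fdr,
                 method = method, reps = as.integer(reps),
                 seed = as.integer(seed), outdir = outdir,
                 knots = as.integer(knots), drop_zeros = drop_zeros,
                 keep_unannotated = keep_unannotated, lib_sizes = lib_sizes),
            class = "run_config")
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys match the
#' arguments of [run_config()]. Values supplied in `...` override the file.
#'
#' @param path config file path.
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop_validation("malformed config line: %s", lines[bad][1])
  vals <- lapply(kv, `[[`, 2L)
  names(vals) <- vapply(kv, `[[`, "", 1L)
  num <- c("fdr", "reps", "seed", "knots")
  vals[names(vals) %in% num] <- lapply(vals[names(vals) %in% num], as.numeric)
  lgl <- c("drop_zeros", "keep_unannotated")
  vals[names(vals) %in% lgl] <- lapply(vals[names(vals) %in% lgl],
                                       function(v) toupper(v) %in% c("TRUE", "1", "YES"))
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

tsv_header <- function(config, extra = character(0)) {
  c(sprintf("tool=gobias version=%s", as.character(packageVersion("gobias"))),
    sprintf("seed=%d method=%s covariate=%s fdr=%g reps=%d",
            config$seed, config$method, config$covariate, config$fdr,
            config$reps),
    extra)
}

write_tsv_commented <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = NA))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full bias-corrected enrichment pipeline
#'
#' Executes the three-step method end to end: call DE genes (Poisson exact
#' test, BH FDR), fit the monotone PWF on the configured bias covariate,
#' and test every category under the configured null. Writes `de.tsv`,
#' `pwf.tsv` and `results.tsv` into the output directory, each with a
#' comment header recording tool version, seed, method and parameters. Any
#' stage error removes partial outputs and propagates with the stage name.
#'
#' @param config a `run_config` (or path to a key=value config file).
#' @return invisibly, a list with `table`, `pwf`, `results`, and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outdir, c("de.tsv", "pwf.tsv", "results.tsv"))
  names(paths) <- c("de", "pwf", "results")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  table <- stage("io", {
    tab <- read_gene_table(config$counts, config$lengths,
                           lib_sizes = config$lib_sizes,
                           drop_zeros = config$drop_zeros)
    map <- read_category_map(config$categories, config$format, tab$gene_id)
    tab <- restrict_to_annotated(tab, map, config$keep_unannotated)
    attr(tab, "map") <- map
    tab
  })
  map <- attr(table, "map")
  message(sprintf("universe: N=%d genes, %d categories",
                  nrow(table), length(map$cat2genes)))

  table <- stage("de", call_de(table, fdr_threshold = config$fdr))
  message(sprintf("DE genes at FDR %g: n=%d", config$fdr, sum(table$de_flag)))

  covariate <- switch(config$covariate,
                      length = table$length_bp,
                      total_count = table$count_1 + table$count_2)
  if (config$covariate == "total_count") {
    keep <- covariate > 0
    if (any(!keep)) {
      message(sprintf("dropping %d zero-count gene(s) for total_count covariate",
                      sum(!keep)))
      table <- as_gene_table(table[keep, ], lib_sizes(table))
      covariate <- covariate[keep]
    }
  }
  pwf <- stage("pwf", fit_pwf(covariate, table$de_flag,
                              n_knots = config$knots,
                              covariate_kind = config$covariate))
  table$pwf_weight <- evaluate_pwf(pwf, covariate)

  results <- stage("enrichment",
                   test_categories(table, map, method = config$method,
                                   reps = config$reps, seed = config$seed))

  hdr <- tsv_header(config)
  write_tsv_commented(
    data.frame(gene_id = table$gene_id, de_pvalue = table$de_pvalue,
               de_qvalue = table$de_qvalue, de_flag = table$de_flag),
    paths["de"], hdr)
  write_tsv_commented(
    data.frame(gene_id = table$gene_id, covariate = covariate,
               pwf_weight = table$pwf_weight),
    paths["pwf"], hdr)
  write_enrichment_results(results, paths["results"],
                           header = tsv_header(config,
                             sprintf("N=%d n_de=%d", attr(results, "N"),
                                     attr(results, "n_de"))))
  ok <- TRUE
  invisible(list(table = table, pwf = pwf, results = results, paths = paths))
}
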