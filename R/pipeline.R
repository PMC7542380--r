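#' Run the full positional-bias / expression pipeline
#'
#' Composes the stages classify -> locate -> bias -> expression (when counts
#' are given) and writes every result table, Circos tracks and a run
#' manifest to `out_dir`. Outputs are deterministic: identical inputs give
#' byte-identical tables.
#'
#' @param genes gene records (data.frame with `cluster_id`).
#' @param chrom_defs chromosome definitions.
#' @param matrix a `pangenome_matrix`.
#' @param counts optional named list: condition -> count data.frame, or
#'   condition -> list of replicate count data.frames (replicates are summed
#'   per gene before RPKM).
#' @param out_dir output directory.
#' @param thresholds [category_thresholds()]; default from the matrix.
#' @param expected_mode,alpha passed to [bias_scan()].
#' @param window,median_scope passed to the expression stage.
#' @param position_rule,use_ter passed to [locate_genes()].
#' @param input_files optional named character vector of input paths whose
#'   md5 checksums go into the manifest.
#' @return List with `loci`, `classification`, `distribution`, `bias`,
#'   `expression` (per condition: profile, trend, quartiles, rank tests) and
#'   `manifest`, invisibly.
#' @export
run_full <- function(genes, chrom_defs, matrix, counts = NULL, out_dir,
                     thresholds = NULL, expected_mode = "uniform",
                     alpha = 0.05, window = 200L,
                     median_scope = "genome",
                     position_rule = "midpoint", use_ter = FALSE,
                     input_files = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
    stages <<- c(stages, name)
    res
  }

  cls <- run_stage("classify", classify_all(matrix, thresholds))
  loci <- run_stage("locate",
    locate_genes(genes, chrom_defs, cls, position_rule = position_rule,
                 use_ter = use_ter))
  dist_tab <- run_stage("distribution", distribution_counts(loci))
  bias_tab <- run_stage("bias",
    bias_scan(dist_tab, alpha = alpha, expected_mode = expected_mode))

  tables <- list(cluster_categories = cls$assignments,
                 category_summary = cls$summary,
                 gene_loci = loci,
                 distribution = dist_tab,
                 bias_tests = bias_tab)

  expression <- NULL
  if (!is.null(counts)) {
    expression <- run_stage("expression", {
      lapply(stats::setNames(names(counts), names(counts)), function(cond) {
        ct <- counts[[cond]]
        if (is.data.frame(ct)) ct <- list(ct)
        ct <- sum_replicates(ct)
        prof <- compute_rpkm(ct, loci)
        prof <- log2_ratio_map(prof, median_scope = median_scope)
        list(profile = prof,
             trend = expression_trend(prof, window = window),
             quartiles = quartile_table(prof, condition = cond),
             rank_tests = expression_rank_scan(prof, condition = cond,
                                               alpha = alpha))
      })
    })
    for (cond in names(expression)) {
      e <- expression[[cond]]
      tables[[paste0("expression_", cond)]] <-
        e$profile$genes[, c("gene_id", "chrom_id", "category", "half",
                            "rel_dist", "recentred_bp", "read_count",
                            "length_bp", "rpkm", "log2_ratio", "imputed")]
      tables[[paste0("trend_", cond)]] <- e$trend
      tables[[paste0("quartiles_", cond)]] <- e$quartiles
      tables[[paste0("rank_tests_", cond)]] <- e$rank_tests
    }
  } else {
    message("[expression] skipped: no counts supplied")
  }

  run_stage("report", {
    write_report_tables(tables, out_dir)
    expr_values <- if (!is.null(expression))
      stats::setNames(expression[[1]]$profile$genes$log2_ratio,
                      expression[[1]]$profile$genes$gene_id) else NULL
    write_circos_tracks(loci, chrom_defs, file.path(out_dir, "circos"),
                        values = expr_values)
  })

  manifest <- list(
    stages = c(stages, if (is.null(counts)) "expression (skipped)"),
    parameters = list(alpha = alpha, window = window,
                      expected_mode = expected_mode,
                      median_scope = median_scope,
                      position_rule = position_rule, use_ter = use_ter,
                      softcore_fraction = cls$thresholds$softcore_fraction,
                      cloud_max = cls$thresholds$cloud_max,
                      n_genomes = cls$thresholds$n_genomes),
    n_clusters = cls$n_clusters,
    n_genes = nrow(loci),
    input_md5 = if (!is.null(input_files))
      as.list(tools::md5sum(input_files)) else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(loci = loci, classification = cls, distribution = dist_tab,
                 bias = bias_tab, expression = expression,
                 manifest = manifest))
}
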