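#' @title Calibration and recovery experiments
#' @description Simulation experiments that quantify whether the pipeline
#'   behaves as designed: type-I calibration of the bias scan under the
#'   uniform null, recovery of the planted positional-bias pattern, and
#'   recovery of the gene-dosage exponent from simulated expression.
#' @name recovery
NULL

scan_one_genome <- function(dataset, genome_id, alpha = 0.05) {
  cls <- classify_all(dataset$matrix,
                      category_thresholds(dataset$config$n_genomes,
                                          dataset$config$softcore_fraction,
                                          dataset$config$cloud_max))
  g <- dataset$genes[dataset$genes$genome_id == genome_id, , drop = FALSE]
  cd <- dataset$chrom_defs[dataset$chrom_defs$genome_id == genome_id, , drop = FALSE]
  loci <- locate_genes(g, cd, cls)
  bias_scan(distribution_counts(loci), alpha = alpha)
}

#' Type-I calibration of the bias scan under the uniform null
#'
#' Simulates unbiased datasets (`bias_strength = 0`), runs the full
#' classify -> locate -> bias pipeline on every genome and pools at least
#' `n_tests` (genome, chromosome, category) chi-square tests. Reports the
#' fraction of raw p-values at or below `alpha` (which should sit near
#' `alpha`) and the fraction flagged by the Bonferroni-adjusted per-dataset
#' scans (which should sit well below it).
#'
#' @param n_tests minimum number of pooled tests; default 2000.
#' @param genes_per_category per-genome category size of the simulated
#'   datasets; default 400.
#' @param alpha nominal level; default 0.05.
#' @param seed RNG seed.
#' @return List with `n_tests`, `rate_raw`, `rate_adjusted`, `se`
#'   (binomial SE of `rate_raw` under the null).
#' @export
type1_calibration <- function(n_tests = 2000L, genes_per_category = 400L,
                              alpha = 0.05, seed = 1L) {
  base <- config_for_genes_per_category(genes_per_category, n_genomes = 6L,
                                        bias_strength = 0)
  tests_per_dataset <- base$n_genomes * 8L   # 2 chromosomes x 4 categories
  n_datasets <- ceiling(n_tests / tests_per_dataset)
  raw <- adj <- logical(0)
  for (i in seq_len(n_datasets)) {
    cfg <- base
    cfg$seed <- seed + i
    ds <- simulate_pangenome(cfg)
    cls <- classify_all(ds$matrix,
                        category_thresholds(cfg$n_genomes,
                                            cfg$softcore_fraction,
                                            cfg$cloud_max))
    loci <- locate_genes(ds$genes, ds$chrom_defs, cls)
    sc <- bias_scan(distribution_counts(loci), alpha = alpha)
    raw <- c(raw, sc$p <= alpha)
    adj <- c(adj, sc$significant)
  }
  list(n_tests = length(raw), rate_raw = mean(raw), rate_adjusted = mean(adj),
       se = sqrt(alpha * (1 - alpha) / length(raw)))
}

#' Recovery of the planted positional-bias pattern
#'
#' Repeatedly simulates a biased pangenome (`bias_strength = b` on the large
#' chromosome only) and checks, per replicate, whether the Bonferroni-
#' adjusted scan of one genome reproduces the expected qualitative pattern:
#' core and softcore significantly upper-biased on the large chromosome,
#' shell and cloud significantly lower-biased, and no significant bias on
#' the small chromosome.
#'
#' @param reps number of replicates; default 50.
#' @param genes_per_category per-genome category size; default 2000.
#' @param b planted bias strength; default 3.
#' @param alpha level; default 0.05.
#' @param seed RNG seed.
#' @return List with `reps`, `pattern_rate` (fraction of replicates showing
#'   the full pattern) and the per-replicate logical vector `pattern`.
#' @export
bias_pattern_recovery <- function(reps = 50L, genes_per_category = 2000L,
                                  b = 3, alpha = 0.05, seed = 1L) {
  base <- config_for_genes_per_category(genes_per_category, n_genomes = 6L,
                                        bias_strength = b)
  pattern <- vapply(seq_len(reps), function(r) {
    cfg <- base
    cfg$seed <- seed + 1000L + r
    ds <- simulate_pangenome(cfg)
    gid <- ds$genes$genome_id[1]
    sc <- scan_one_genome(ds, gid, alpha = alpha)
    chr1 <- grepl("_chr1$", sc$chrom_id)
    ok_dir <- function(cat, dir) {
      row <- sc[chr1 & sc$category == cat, ]
      nrow(row) == 1 && row$significant && row$direction == dir
    }
    all(ok_dir("core", "upper"), ok_dir("softcore", "upper"),
        ok_dir("shell", "lower"), ok_dir("cloud", "lower")) &&
      !any(sc$significant[!chr1])
  }, TRUE)
  list(reps = reps, pattern_rate = mean(pattern), pattern = pattern)
}

#' Recovery of the gene-dosage exponent from simulated expression
#'
#' Simulates fast-growth counts under dosage exponent `k` with positionally
#' unbiased genes, runs the expression stage and fits the slope of
#' log2(RPKM) against relative ori distance on the large chromosome; the
#' planted value is `-k`. Also, over `slow_reps` slow-growth replicates
#' (`k = 0`), records how often the core upper-vs-lower rank test is
#' non-significant (it should usually be, mirroring position-independent
#' core expression at slow growth).
#'
#' @param k planted dosage exponent; default 1.5.
#' @param sigma multiplicative noise sd (log scale); default 0.3.
#' @param n_genes approximate number of large-chromosome genes used for the
#'   slope fit; default 3000.
#' @param slow_reps slow-growth replicates; default 30.
#' @param alpha level; default 0.05.
#' @param seed RNG seed.
#' @return List with `slope`, `se`, `within_2se` (planted `-k` within 2 SEs),
#'   `n_fit`, and `core_nonsig_rate` at slow growth.
#' @export
dosage_recovery <- function(k = 1.5, sigma = 0.3, n_genes = 3000L,
                            slow_reps = 30L, alpha = 0.05, seed = 1L) {
  # genes_per_category g gives ~4g genes per genome, ~64% on the large
  # chromosome: g = n_genes / (4 * 0.64)
  g <- ceiling(n_genes / (4 * 0.64))
  base <- config_for_genes_per_category(g, n_genomes = 6L,
                                        bias_strength = 0,
                                        dosage_exponent_k = k,
                                        noise_sd_log = sigma)
  base$seed <- seed + 5000L
  ds <- simulate_pangenome(base)
  cls <- classify_all(ds$matrix,
                      category_thresholds(base$n_genomes,
                                          base$softcore_fraction,
                                          base$cloud_max))
  gid <- ds$genes$genome_id[1]
  loci <- locate_genes(ds$genes[ds$genes$genome_id == gid, , drop = FALSE],
                       ds$chrom_defs[ds$chrom_defs$genome_id == gid, , drop = FALSE],
                       cls)
  ct <- simulate_counts(ds, base, "fast", genome_id = gid)[[1]]
  prof <- log2_ratio_map(compute_rpkm(ct, loci))
  chr1 <- paste0(gid, "_chr1")
  sl <- dosage_slope(prof, chrom = chr1)

  core_nonsig <- vapply(seq_len(slow_reps), function(r) {
    cfg <- base
    cfg$seed <- seed + 6000L + r
    dsr <- simulate_pangenome(cfg)
    gidr <- dsr$genes$genome_id[1]
    clsr <- classify_all(dsr$matrix,
                         category_thresholds(cfg$n_genomes,
                                             cfg$softcore_fraction,
                                             cfg$cloud_max))
    locir <- locate_genes(dsr$genes[dsr$genes$genome_id == gidr, , drop = FALSE],
                          dsr$chrom_defs[dsr$chrom_defs$genome_id == gidr, , drop = FALSE],
                          clsr)
    ctr <- simulate_counts(dsr, cfg, "slow", genome_id = gidr)[[1]]
    profr <- log2_ratio_map(compute_rpkm(ctr, locir))
    rs <- expression_rank_scan(profr, chrom = paste0(gidr, "_chr1"),
                               alpha = alpha)
    !rs$significant[rs$category == "core"]
  }, TRUE)

  list(slope = sl$slope, se = sl$se,
       within_2se = abs(sl$slope - (-k)) <= 2 * sl$se,
       n_fit = sl$n, core_nonsig_rate = mean(core_nonsig))
}

#' Run the full calibration and recovery suite
#'
#' Executes [type1_calibration()], [bias_pattern_recovery()] and
#' [dosage_recovery()] at their study conditions and returns a pass/fail
#' summary per property.
#'
#' @param seed RNG seed.
#' @param reps replicates for the bias-pattern experiment; default 50.
#' @param n_tests pooled tests for the type-I calibration; default 2000.
#' @param genes_per_category category size for the bias-pattern experiment;
#'   default 2000.
#' @param slow_reps slow-growth replicates for the dosage experiment;
#'   default 30.
#' @param out optional TSV path for the summary.
#' @return data.frame `property`, `value`, `threshold`, `pass`.
#' @export
run_recovery_suite <- function(seed = 1L, reps = 50L, n_tests = 2000L,
                               genes_per_category = 2000L, slow_reps = 30L,
                               out = NULL) {
  t1 <- type1_calibration(n_tests = n_tests, seed = seed)
  br <- bias_pattern_recovery(reps = reps,
                              genes_per_category = genes_per_category,
                              seed = seed)
  dr <- dosage_recovery(slow_reps = slow_reps, seed = seed)
  summary <- data.frame(
    property = c("type1_rate_raw", "type1_rate_adjusted",
                 "bias_pattern_rate", "dosage_slope", "core_nonsig_rate_slow"),
    value = c(t1$rate_raw, t1$rate_adjusted, br$pattern_rate,
              dr$slope, dr$core_nonsig_rate),
    threshold = c(0.05 + 3 * t1$se, 0.05, 0.95, -1.5, 0.90),
    pass = c(t1$rate_raw <= 0.05 + 3 * t1$se,
             t1$rate_adjusted <= 0.05,
             br$pattern_rate >= 0.95,
             dr$within_2se,
             dr$core_nonsig_rate >= 0.90),
    stringsAsFactors = FALSE
  )
  if (!is.null(out)) write_report_tables(summary, out)
  summary
}
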