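small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 5, n_genomes = 6L, n_clusters = 1500L,
         chr1_length_bp = 800000, chr2_length_bp = 450000,
         ori1_bp = 50000, ori2_bp = 20000,
         occupancy_mix = c(core = 0.25, softcore = 0.2,
                           shell = 0.25, cloud = 0.3)),
    list(...))
  do.call(synthetic_config, args)
}

test_that("the same seed reproduces a dataset exactly; seeds differ", {
  d1 <- simulate_pangenome(small_cfg())
  d2 <- simulate_pangenome(small_cfg())
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$matrix$counts, d2$matrix$counts)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_pangenome(small_cfg(seed = 6))
  expect_false(identical(d1$genes$start_bp, d3$genes$start_bp))
})

test_that("occupancy histogram matches the configured mixture", {
  cfg <- small_cfg(n_clusters = 4000L)
  ds <- simulate_pangenome(cfg)
  cls <- classify_all(ds$matrix, category_thresholds(6))
  s <- cls$summary
  for (cat in c("core", "softcore", "shell", "cloud")) {
    p <- cfg$occupancy_mix[[cat]]
    got <- s$count_exclusive[s$category == cat] / 4000
    expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / 4000))
  }
  # matrix occupancies consistent with emitted genes
  occ <- occupancy(ds$matrix)
  genes_per_cluster <- table(ds$genes$cluster_id)
  expect_equal(unname(occ[names(genes_per_cluster)]),
               as.integer(genes_per_cluster))
})

test_that("planted Beta position law has the expected mean ori distance", {
  b <- 3
  cfg <- config_for_genes_per_category(700, 6, bias_strength = b, seed = 7)
  ds <- simulate_pangenome(cfg)
  tr <- ds$truth[grepl("_chr1$", ds$truth$chrom_id), ]
  u_core <- tr$u[tr$category == "core"]
  # Beta(1, 1+b): mean 1/(2+b)
  expect_lt(abs(mean(u_core) - 1 / (2 + b)),
            3 * sd(u_core) / sqrt(length(u_core)))
  u_shell <- tr$u[tr$category == "shell"]
  expect_lt(abs(mean(u_shell) - (1 + b) / (2 + b)),
            3 * sd(u_shell) / sqrt(length(u_shell)))
  # no bias planted on the small chromosome
  u2 <- ds$truth$u[grepl("_chr2$", ds$truth$chrom_id)]
  expect_lt(abs(mean(u2) - 0.5), 3 * sd(u2) / sqrt(length(u2)))
})

test_that("b = 0 gives per-category upper fractions near one half", {
  cfg <- small_cfg(bias_strength = 0)
  ds <- simulate_pangenome(cfg)
  for (cat in c("core", "cloud")) {
    h <- ds$truth$half[ds$truth$category == cat]
    expect_lt(abs(mean(h == "upper") - 0.5), 4 * sqrt(0.25 / length(h)))
  }
})

test_that("truth halves agree with the geometry module on emitted coordinates", {
  ds <- simulate_pangenome(small_cfg())
  cls <- classify_all(ds$matrix, category_thresholds(6))
  loci <- locate_genes(ds$genes, ds$chrom_defs, cls)
  m <- match(ds$truth$gene_id, loci$gene_id)
  expect_equal(loci$half[m], ds$truth$half)
  expect_equal(loci$rel_dist[m], ds$truth$u)
  # true categories equal matrix-derived categories (single-copy genes)
  expect_equal(loci$category[m], ds$truth$category)
  # truth covers every gene exactly once
  expect_equal(sort(ds$truth$gene_id), sort(ds$genes$gene_id))
})

test_that("dosage law: ori/ter expectation ratio is 2^k and slope is recoverable", {
  # deterministic part: expected dosage at u=0 vs u=1 under k=1
  cfg <- small_cfg(dosage_exponent_k = 1)
  ds <- simulate_pangenome(cfg)
  expect_equal(max(ds$truth$dosage_fast[grepl("chr1", ds$truth$chrom_id)]) /
                 min(ds$truth$dosage_fast), 2, tolerance = 0.01)
  # k = 0, sigma = 0: equal-length genes get equal expected counts
  cfg0 <- small_cfg(dosage_exponent_k = 0, noise_sd_log = 0,
                    category_baseline = c(core = 1, softcore = 1,
                                          shell = 1, cloud = 1))
  ds0 <- simulate_pangenome(cfg0)
  ct <- simulate_counts(ds0, cfg0, "fast")[[1]]
  g1 <- ds0$genes[ds0$genes$genome_id == ds0$genes$genome_id[1], ]
  len <- g1$end_bp - g1$start_bp
  cpk <- ct$read_count[match(g1$gene_id, ct$gene_id)] / (len / 1000)
  # counts per kb flat in expectation: regression slope on u ~ 0
  tr0 <- ds0$truth[match(g1$gene_id, ds0$truth$gene_id), ]
  fit <- lm(cpk ~ tr0$u)
  expect_lt(abs(coef(fit)[2]), 3 * summary(fit)$coefficients[2, 2])
})

test_that("counts simulation is seed-deterministic and condition-sensitive", {
  cfg <- small_cfg()
  ds <- simulate_pangenome(cfg)
  c1 <- simulate_counts(ds, cfg, "fast")[[1]]
  c2 <- simulate_counts(ds, cfg, "fast")[[1]]
  expect_identical(c1, c2)
  c3 <- simulate_counts(ds, cfg, "slow")[[1]]
  expect_false(identical(c1$read_count, c3$read_count))
  expect_equal(sum(c1$read_count), cfg$library_size, tolerance = 0.01)
  reps <- simulate_counts(ds, cfg, "fast", n_reps = 3)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$read_count, reps[[2]]$read_count))
})

test_that("infeasible occupancy ranges are rejected", {
  expect_error(simulate_pangenome(synthetic_config(n_genomes = 3L)),
               "infeasible")
  expect_error(config_for_genes_per_category(100, n_genomes = 3L),
               "shell range")
})

test_that("written dataset files reload into the same structures", {
  cfg <- small_cfg(n_clusters = 200L)
  ds <- simulate_pangenome(cfg)
  out <- withr::local_tempdir()
  files <- write_synthetic_dataset(ds, out,
                                   counts = list(fast = simulate_counts(ds, cfg, "fast")))
  expect_true(all(file.exists(files)))
  m <- read_pangenome_matrix(file.path(out, "pangenome_matrix.tsv"))
  expect_equal(m$counts, ds$matrix$counts)
  defs <- read_ori_table(file.path(out, "ori_table.csv"))
  expect_equal(nrow(defs), 12L)                      # 6 genomes x 2 chromosomes
  gid <- ds$genes$genome_id[1]
  back <- read_gff(file.path(out, paste0(gid, ".gff3")), gid)
  orig <- ds$genes[ds$genes$genome_id == gid, ]
  m2 <- match(orig$gene_id, back$genes$gene_id)
  expect_equal(back$genes$start_bp[m2], orig$start_bp)
  expect_equal(back$genes$cluster_id[m2], orig$cluster_id)
})
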