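#' @title Synthetic pangenome and expression data
#' @description Generates bipartite-genome datasets with the statistical
#'   structure the analysis assumes: a U-shaped cluster-occupancy mixture,
#'   category-dependent positional bias along the ori-ter axis of the large
#'   chromosome (none on the small one), and read counts whose expectation
#'   decays with distance from ori via a multifork gene-dosage exponent
#'   (strong at fast growth, zero at slow growth) with multiplicative noise.
#'   Every dataset carries a truth table so parameter recovery is
#'   quantifiable.
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' All parameters of the synthetic generator, with desk-scale defaults.
#' The occupancy mixture defaults echo the empirical pangenome proportions
#' (roughly 1% core, 2% softcore, 23% shell, 74% cloud). The positional law
#' draws the relative distance to ori `u` from Beta(1, 1 + b) for
#' core/softcore and Beta(1 + b, 1) for shell/cloud on the large chromosome
#' (uniform when `b = 0` or on the small chromosome). The dosage law gives a
#' gene at relative distance `u` copy number `2^(k * (1 - u))`.
#'
#' @param seed integer; fully determines the dataset.
#' @param n_genomes number of genomes N; default 12.
#' @param chr1_length_bp,chr2_length_bp chromosome lengths; defaults
#'   3,200,000 and 1,800,000 bp (large/small chromosome of a bipartite
#'   genome).
#' @param ori1_bp,ori2_bp replication origin positions (0-based).
#' @param n_clusters number of orthologous clusters; default 6000
#'   (desk-scale).
#' @param occupancy_mix probabilities (core, softcore, shell, cloud).
#' @param bias_strength Beta bias parameter `b >= 0`; 0 = uniform positions.
#' @param chr1_bias_on plant positional bias on the large chromosome only
#'   (default `TRUE`; the small chromosome stays unbiased).
#' @param dosage_exponent_k dosage exponent at fast growth (slow growth uses
#'   0); default 1.5.
#' @param chr2_dosage_flat no dosage gradient on the small chromosome
#'   (default `TRUE`).
#' @param category_baseline mean expression multipliers per category.
#' @param noise_sd_log sd of the multiplicative log-normal expression noise
#'   (natural-log scale); default 0.3.
#' @param library_size expected total read count per sample; default 5e6.
#' @param gene_length_meanlog,gene_length_sdlog log-normal law of gene
#'   lengths in bp.
#' @param softcore_fraction,cloud_max classification thresholds used both to
#'   draw occupancies and downstream.
#' @param slow_residual_k optional residual gradient applied to softcore,
#'   shell and cloud genes at slow growth (a stand-in for the non-dosage
#'   mechanisms that keep non-core categories biased at slow growth; default
#'   0 = off).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genomes = 12L,
                             chr1_length_bp = 3200000,
                             chr2_length_bp = 1800000,
                             ori1_bp = 200000,
                             ori2_bp = 100000,
                             n_clusters = 6000L,
                             occupancy_mix = c(core = 0.012, softcore = 0.018,
                                               shell = 0.23, cloud = 0.74),
                             bias_strength = 3,
                             chr1_bias_on = TRUE,
                             dosage_exponent_k = 1.5,
                             chr2_dosage_flat = TRUE,
                             category_baseline = c(core = 8, softcore = 4,
                                                   shell = 2, cloud = 1),
                             noise_sd_log = 0.3,
                             library_size = 5e6,
                             gene_length_meanlog = log(900),
                             gene_length_sdlog = 0.35,
                             softcore_fraction = 0.95,
                             cloud_max = 2L,
                             slow_residual_k = 0) {
  stopifnot(abs(sum(occupancy_mix) - 1) < 1e-8,
            chr1_length_bp > 0, chr2_length_bp > 0,
            bias_strength >= 0, dosage_exponent_k >= 0, noise_sd_log >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Derive a configuration targeting a per-genome gene count per category
#'
#' Solves the occupancy mixture and cluster count so that each genome is
#' expected to carry about `genes_per_category` genes of every category:
#' the expected per-genome gene count of a category equals
#' `n_clusters_cat * E[occupancy_cat] / N`.
#'
#' @param genes_per_category target genes per category per genome.
#' @param n_genomes number of genomes (small values keep datasets light);
#'   default 6.
#' @param ... further overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
config_for_genes_per_category <- function(genes_per_category = 2000,
                                          n_genomes = 6L, ...) {
  N <- n_genomes
  sc_min <- softcore_threshold(N, 0.95)
  if (sc_min <= 3) stop("n_genomes too small for a non-empty shell range")
  e_occ <- c(core = N,
             softcore = mean(sc_min:(N - 1)),
             shell = mean(3:(sc_min - 1)),
             cloud = 1.5)
  n_cat <- round(genes_per_category * N / e_occ)
  synthetic_config(n_genomes = N, n_clusters = as.integer(sum(n_cat)),
                   occupancy_mix = n_cat / sum(n_cat), ...)
}

#' Simulate a pangenome with planted positional bias (structure only)
#'
#' Draws cluster occupancies from the four-component mixture (core: N;
#' softcore: uniform on \\[softcore_min, N - 1\\]; shell: uniform on
#' \\[3, softcore_min - 1\\]; cloud: uniform on \\{1, 2\\}), assigns each
#' cluster a home chromosome (probability proportional to length), places
#' each present gene at a relative ori distance drawn from the category's
#' Beta law, on either side of ori with probability 1/2, and gives it a
#' log-normal length. Genes are shifted so they never span linear coordinate
#' 0 (emitted GFF3 stays valid); overlaps are not prevented.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_dataset`: list with `chrom_defs`, `genes`, `matrix`
#'   (a `pangenome_matrix`), `truth` (per-gene true category, `u`, half and
#'   expected fast-growth dosage) and `config`.
#' @export
simulate_pangenome <- function(config) {
  set.seed(config$seed)
  N <- config$n_genomes
  genome_ids <- sprintf("G%02d", seq_len(N))
  sc_min <- softcore_threshold(N, config$softcore_fraction)
  if (sc_min <= 3 || sc_min > N)
    stop("infeasible occupancy ranges: softcore_min = ", sc_min,
         " with N = ", N)
  cats <- c("core", "softcore", "shell", "cloud")
  cat_of <- sample(cats, config$n_clusters, replace = TRUE,
                   prob = config$occupancy_mix[cats])
  draw_range <- function(lo, hi, n)
    (lo:hi)[sample.int(hi - lo + 1, n, replace = TRUE)]
  occ <- integer(config$n_clusters)
  occ[cat_of == "core"] <- N
  occ[cat_of == "softcore"] <- draw_range(sc_min, N - 1, sum(cat_of == "softcore"))
  occ[cat_of == "shell"] <- draw_range(3, sc_min - 1, sum(cat_of == "shell"))
  occ[cat_of == "cloud"] <- draw_range(1, config$cloud_max, sum(cat_of == "cloud"))

  cluster_ids <- sprintf("CL%06d", seq_len(config$n_clusters))
  counts <- matrix(0L, config$n_clusters, N,
                   dimnames = list(cluster_ids, genome_ids))
  for (i in seq_len(config$n_clusters))
    counts[i, sample.int(N, occ[i])] <- 1L

  L1 <- config$chr1_length_bp; L2 <- config$chr2_length_bp
  p1 <- L1 / (L1 + L2)
  home <- sample(c("chr1", "chr2"), config$n_clusters, replace = TRUE,
                 prob = c(p1, 1 - p1))

  present <- which(counts == 1L, arr.ind = TRUE)
  ci <- present[, 1]; gi <- present[, 2]
  n_genes <- nrow(present)
  g_cat <- cat_of[ci]
  g_chrom <- home[ci]
  on1 <- g_chrom == "chr1"
  L <- ifelse(on1, L1, L2)
  ori <- ifelse(on1, config$ori1_bp, config$ori2_bp)

  b <- config$bias_strength
  u <- stats::runif(n_genes)
  if (b > 0 && config$chr1_bias_on) {
    toward_ori <- on1 & g_cat %in% c("core", "softcore")
    toward_ter <- on1 & g_cat %in% c("shell", "cloud")
    u[toward_ori] <- stats::rbeta(sum(toward_ori), 1, 1 + b)
    u[toward_ter] <- stats::rbeta(sum(toward_ter), 1 + b, 1)
  }
  side <- sample(c(-1L, 1L), n_genes, replace = TRUE)
  mid <- (ori + side * round(u * L / 2)) %% L
  len <- pmax(90, round(stats::rlnorm(n_genes, config$gene_length_meanlog,
                                      config$gene_length_sdlog)))
  start <- mid - floor(len / 2)
  start <- pmax(0, pmin(start, L - len))   # keep genes off the wrap point
  end <- start + len

  mid_actual <- gene_midpoint(start, end, L)
  d <- circular_distance(mid_actual, ori, L)
  u_actual <- 2 * d / L

  ord <- order(gi, g_chrom, start)
  genome_of <- genome_ids[gi][ord]
  per_genome_idx <- stats::ave(seq_along(ord), genome_of, FUN = seq_along)
  gene_id <- sprintf("%s_g%05d", genome_of, per_genome_idx)

  genes <- data.frame(
    gene_id = gene_id,
    genome_id = genome_of,
    chrom_id = paste0(genome_of, "_", g_chrom[ord]),
    start_bp = start[ord], end_bp = end[ord],
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    cluster_id = cluster_ids[ci][ord],
    stringsAsFactors = FALSE
  )
  k <- config$dosage_exponent_k
  truth <- data.frame(
    gene_id = gene_id,
    genome_id = genome_of,
    chrom_id = genes$chrom_id,
    category = g_cat[ord],
    u = u_actual[ord],
    half = ifelse(u_actual[ord] < 0.5, "upper", "lower"),
    dosage_fast = ifelse(g_chrom[ord] == "chr2" & config$chr2_dosage_flat,
                         1, 2 ^ (k * (1 - u_actual[ord]))),
    stringsAsFactors = FALSE
  )
  chrom_defs <- data.frame(
    chrom_id = c(paste0(genome_ids, "_chr1"), paste0(genome_ids, "_chr2")),
    genome_id = rep(genome_ids, 2),
    length_bp = rep(c(L1, L2), each = N),
    ori_bp = rep(c(config$ori1_bp, config$ori2_bp), each = N),
    ter_bp = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(chrom_defs = chrom_defs, genes = genes,
                 matrix = pangenome_matrix(counts), truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$genes), "genes,",
      nrow(x$matrix$counts), "clusters,", x$config$n_genomes, "genomes\n")
  invisible(x)
}

#' Simulate per-CDS read counts under a growth condition
#'
#' Expected expression of gene g is
#' `baseline(category) * 2^(k_eff * (1 - u_g)) * exp(eps_g)` with
#' `eps_g ~ Normal(0, noise_sd_log^2)`. Fast growth uses
#' `k_eff = dosage_exponent_k` on the large chromosome (and on the small one
#' unless `chr2_dosage_flat`); slow growth uses `k_eff = 0` everywhere,
#' except an optional `slow_residual_k` for softcore/shell/cloud genes.
#' Counts are Poisson with mean proportional to expression times gene length
#' in kb, scaled so the sample total is about `library_size`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param config its configuration (defaults to `dataset$config`).
#' @param condition `"fast"` or `"slow"`.
#' @param genome_id which genome to sequence; default the first.
#' @param n_reps number of replicate samples; default 1.
#' @return List of count data.frames (`gene_id`, `read_count`), one per
#'   replicate.
#' @export
simulate_counts <- function(dataset, config = dataset$config,
                            condition = c("fast", "slow"),
                            genome_id = NULL, n_reps = 1L) {
  condition <- match.arg(condition)
  if (is.null(genome_id)) genome_id <- dataset$genes$genome_id[1]
  set.seed(config$seed + 101L * match(condition, c("fast", "slow")) +
             7L * match(genome_id, unique(dataset$genes$genome_id)))
  tr <- dataset$truth[dataset$truth$genome_id == genome_id, , drop = FALSE]
  g <- dataset$genes[match(tr$gene_id, dataset$genes$gene_id), , drop = FALSE]
  on2 <- grepl("_chr2$", tr$chrom_id)

  k_eff <- if (condition == "fast") {
    ifelse(on2 & config$chr2_dosage_flat, 0, config$dosage_exponent_k)
  } else {
    ifelse(!on2 & tr$category != "core", config$slow_residual_k, 0)
  }
  base <- config$category_baseline[tr$category]
  len_kb <- (g$end_bp - g$start_bp) / 1000
  lapply(seq_len(n_reps), function(r) {
    e <- base * 2 ^ (k_eff * (1 - tr$u)) *
      exp(stats::rnorm(nrow(tr), 0, config$noise_sd_log))
    lambda <- e * len_kb
    lambda <- lambda / sum(lambda) * config$library_size
    data.frame(gene_id = tr$gene_id,
               read_count = stats::rpois(nrow(tr), lambda),
               stringsAsFactors = FALSE)
  })
}

#' Write the per-gene truth table
#'
#' One row per generated gene: true category, relative ori distance `u`,
#' half, and expected fast-growth dosage — the substrate of every recovery
#' experiment.
#'
#' @param dataset a `synthetic_dataset`.
#' @param path optional TSV path; when given the table is written there.
#' @return The truth data.frame, invisibly when `path` is given.
#' @export
truth_report <- function(dataset, path = NULL) {
  tr <- dataset$truth
  if (!is.null(path)) {
    write_report_tables(tr, path)
    return(invisible(tr))
  }
  tr
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits one GFF3 per genome, an ori CSV, the pangenome matrix TSV, the
#' truth TSV and, when supplied, one counts TSV per condition/replicate.
#'
#' @param dataset a `synthetic_dataset`.
#' @param out_dir output directory.
#' @param counts optional named list (condition -> list of count tables).
#' @return Character vector of files written, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, out_dir, counts = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (gid in unique(dataset$genes$genome_id)) {
    f <- file.path(out_dir, paste0(gid, ".gff3"))
    write_gff(dataset$genes[dataset$genes$genome_id == gid, , drop = FALSE],
              dataset$chrom_defs[dataset$chrom_defs$genome_id == gid, , drop = FALSE],
              f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "ori_table.csv")
  utils::write.csv(dataset$chrom_defs[, c("chrom_id", "length_bp", "ori_bp", "ter_bp")],
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "pangenome_matrix.tsv")
  write_pangenome_matrix(dataset$matrix, f)
  files <- c(files, f)
  f <- file.path(out_dir, "truth.tsv")
  truth_report(dataset, f)
  files <- c(files, f)
  for (cond in names(counts)) {
    tabs <- counts[[cond]]
    for (r in seq_along(tabs)) {
      f <- file.path(out_dir, sprintf("counts_%s_rep%d.tsv", cond, r))
      write_counts(tabs[[r]], f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
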