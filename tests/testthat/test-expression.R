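make_profile <- function(rpkms, halves = NULL, categories = NULL,
                         chrom_id = "c1") {
  n <- length(rpkms)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom_id = chrom_id,
    category = if (is.null(categories)) rep("core", n) else categories,
    half = if (is.null(halves)) rep(c("upper", "lower"), length.out = n)
           else halves,
    rel_dist = seq(0, 1, length.out = n),
    recentred_bp = seq_len(n),
    rpkm = rpkms,
    stringsAsFactors = FALSE)
  structure(list(genes = genes, total_mapped = 1e6,
                 median_rpkm = median(rpkms)),
            class = "expression_profile")
}

test_that("RPKM formula: unit case and derived case", {
  loci <- data.frame(gene_id = c("a", "b", "c"), genome_id = "G1",
                     chrom_id = "c1", start_bp = c(0, 2000, 5000),
                     end_bp = c(1000, 4000, 5100), strand = "+",
                     stringsAsFactors = FALSE)
  counts <- data.frame(gene_id = c("a", "b"),
                       read_count = c(1000, 500))
  # unit case needs total 1e6: pad with a filler gene
  loci2 <- rbind(loci, data.frame(gene_id = "pad", genome_id = "G1",
                                  chrom_id = "c1", start_bp = 6000,
                                  end_bp = 7000, strand = "+"))
  counts2 <- rbind(counts, data.frame(gene_id = "pad",
                                      read_count = 1e6 - 1500))
  prof <- compute_rpkm(counts2, loci2)
  expect_equal(prof$total_mapped, 1e6)
  expect_equal(prof$genes$rpkm[prof$genes$gene_id == "a"], 1000)
  expect_equal(prof$genes$rpkm[prof$genes$gene_id == "c"], 0)  # no count row

  # 500 reads, 2 kb gene, 2e6 total -> 125
  counts3 <- data.frame(gene_id = c("a", "b"), read_count = c(2e6 - 500, 500))
  prof3 <- compute_rpkm(counts3, loci)
  expect_equal(prof3$genes$rpkm[prof3$genes$gene_id == "b"], 125)

  expect_error(compute_rpkm(data.frame(gene_id = "a", read_count = 0), loci),
               "zero")
})

test_that("RPKM linearity: scaling all counts is a no-op; scaling one gene scales it", {
  loci <- make_genes(20, L = 50000, len = 500, seed = 31)
  set.seed(32)
  counts <- data.frame(gene_id = loci$gene_id,
                       read_count = rpois(20, 500) + 1)
  r1 <- compute_rpkm(counts, loci)$genes$rpkm
  counts2 <- transform(counts, read_count = read_count * 2)
  expect_equal(compute_rpkm(counts2, loci)$genes$rpkm, r1)
  # doubling one gene with total held fixed doubles its RPKM
  counts3 <- counts
  counts3$read_count[1] <- counts3$read_count[1] * 2
  counts3$read_count[2] <- counts3$read_count[2] -
    counts$read_count[1]          # keep total constant
  r3 <- compute_rpkm(counts3, loci)$genes$rpkm
  expect_equal(r3[1], 2 * r1[1])
})

test_that("log2 ratio map centres at the median and imputes zeros at eps", {
  prof <- make_profile(c(1, 2, 4))
  m <- log2_ratio_map(prof)
  expect_equal(m$genes$log2_ratio, c(-1, 0, 1))
  expect_false(any(m$genes$imputed))

  # odd n, no imputation: median of ratios is 0
  prof2 <- make_profile(c(5, 1, 9, 2, 7))
  m2 <- log2_ratio_map(prof2)
  expect_equal(median(m2$genes$log2_ratio), 0)

  # zero-count gene: eps = half the smallest nonzero rpkm
  prof3 <- make_profile(c(0, 8, 2, 2, 16))
  m3 <- log2_ratio_map(prof3)
  expect_true(m3$genes$imputed[1])
  expect_equal(m3$genes$log2_ratio[1], log2((2 / 2) / 2))
  expect_error(log2_ratio_map(make_profile(c(0, 0, 0, 1))), "median RPKM")
})

test_that("per-chromosome median scope centres each chromosome", {
  prof <- make_profile(c(1, 2, 4, 10, 20, 40),
                       chrom_id = rep(c("c1", "c2"), each = 3))
  m <- log2_ratio_map(prof, median_scope = "per_chromosome")
  expect_equal(m$genes$log2_ratio, c(-1, 0, 1, -1, 0, 1))
})

test_that("sliding trend: identity at window 1, constants, circular wrap", {
  expect_equal(sliding_trend(c(5, 5, 5, 5), 3), rep(5, 4))
  x <- rnorm(10)
  expect_equal(sliding_trend(x, 1), x)
  expect_equal(sliding_trend(c(0, 3, 6), 3), c(3, 3, 3))  # wrap-around means
  expect_error(sliding_trend(1:5, 10), "smaller window")
})

test_that("sliding trend matches brute-force circular moving average", {
  set.seed(33)
  for (w in c(2, 3, 4, 7, 10)) {
    x <- rnorm(25)
    expect_equal(sliding_trend(x, w), brute_circular_ma(x, w),
                 info = paste("window", w))
  }
})

test_that("circular trend preserves the mean and commutes with constants", {
  set.seed(34)
  x <- rnorm(100)
  tr <- sliding_trend(x, 10)
  expect_equal(mean(tr), mean(x))
  expect_equal(sliding_trend(x + 2.5, 10), tr + 2.5)
})

test_that("quartiles use linear interpolation between order statistics", {
  prof <- make_profile(c(1, 2, 3, 4, 5), halves = rep("upper", 5))
  qt <- quartile_table(prof, condition = "cond")
  up <- qt[qt$half == "upper" & qt$category == "core", ]
  expect_equal(unlist(up[c("Q1", "Q2", "Q3", "Max")], use.names = FALSE),
               c(2, 3, 4, 5))
  expect_true(all(with(stats::na.omit(qt), Q1 <= Q2 & Q2 <= Q3 & Q3 <= Max)))
  lo <- qt[qt$half == "lower", ]
  expect_equal(lo$n_genes, 0L)                       # empty cell row kept
  expect_true(is.na(lo$Q1))

  # single value: all quartiles equal it
  prof1 <- make_profile(c(7, 7), halves = c("upper", "lower"))
  qt1 <- quartile_table(prof1)
  expect_equal(qt1$Q1, c(7, 7))
  expect_equal(qt1$Max, c(7, 7))
})

test_that("quartile table has the per-condition category x half layout", {
  set.seed(35)
  prof <- make_profile(rexp(80),
                       halves = sample(c("upper", "lower"), 80, TRUE),
                       categories = sample(c("core", "softcore", "shell",
                                             "cloud"), 80, TRUE))
  qt <- quartile_table(prof, condition = "fast")
  expect_equal(nrow(qt), 8L)                         # 4 categories x 2 halves
  expect_equal(unique(qt$condition), "fast")
  expect_equal(sum(qt$n_genes), 80L)
})

test_that("rank test matches exact enumeration on small samples", {
  r <- rank_test_upper_vs_lower(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  r <- rank_test_upper_vs_lower(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)                       # 2/20 orderings
  expect_equal(r$p_value, brute_ranksum_p(c(1, 2, 3), c(10, 11, 12)))
  set.seed(36)
  for (i in 1:30) {
    x <- sample(1:1000, sample(3:6, 1))              # tie-free by construction
    y <- sample(1:1000, sample(3:6, 1)) + 0.5
    expect_equal(rank_test_upper_vs_lower(x, y)$p_value,
                 brute_ranksum_p(x, y), tolerance = 1e-10)
  }
  expect_error(rank_test_upper_vs_lower(numeric(0), 1:3), "non-empty")
})

test_that("planted twofold median shift is detected after Bonferroni", {
  set.seed(37)
  n <- 500
  prof <- make_profile(c(2 * rlnorm(n), rlnorm(n)),
                       halves = rep(c("upper", "lower"), each = n))
  sc <- expression_rank_scan(prof)
  expect_true(sc$significant[sc$category == "core"])
  expect_lte(sc$p_adjusted[1], 0.05)
  expect_gt(sc$median_upper[1], sc$median_lower[1])
})

test_that("replicate counts sum per gene", {
  a <- data.frame(gene_id = c("g1", "g2"), read_count = c(5, 7))
  b <- data.frame(gene_id = c("g2", "g1"), read_count = c(3, 1))
  s <- sum_replicates(list(a, b))
  expect_equal(s$read_count[match(c("g1", "g2"), s$gene_id)], c(6, 10))
})
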