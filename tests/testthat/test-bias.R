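test_that("distribution counts match a brute-force tally", {
  set.seed(21)
  loci <- data.frame(
    genome_id = sample(c("G1", "G2"), 300, replace = TRUE),
    chrom_id = sample(c("c1", "c2"), 300, replace = TRUE),
    category = sample(c("core", "softcore", "shell", "cloud"), 300,
                      replace = TRUE),
    half = sample(c("upper", "lower"), 300, replace = TRUE),
    stringsAsFactors = FALSE)
  tab <- distribution_counts(loci)
  for (i in seq_len(nrow(tab))) {
    sel <- loci$genome_id == tab$genome_id[i] &
      loci$chrom_id == tab$chrom_id[i] & loci$category == tab$category[i]
    expect_equal(tab$upper_count[i], sum(sel & loci$half == "upper"))
    expect_equal(tab$lower_count[i], sum(sel & loci$half == "lower"))
  }
  # per chromosome, percentages over all categories and halves sum to 100
  for (g in unique(tab$genome_id)) for (ch in unique(tab$chrom_id)) {
    rows <- tab$genome_id == g & tab$chrom_id == ch
    if (any(rows))
      expect_equal(sum(tab$pct_upper_of_chrom_cds[rows] +
                         tab$pct_lower_of_chrom_cds[rows]), 100)
  }
})

test_that("distribution percentages for a simple case", {
  loci <- data.frame(genome_id = "G1", chrom_id = "c1", category = "core",
                     half = rep(c("upper", "lower"), c(7, 3)),
                     stringsAsFactors = FALSE)
  tab <- distribution_counts(loci)
  expect_equal(tab$upper_count, 7L)
  expect_equal(tab$lower_count, 3L)
  expect_equal(tab$pct_upper_of_chrom_cds, 70)
  expect_equal(tab$pct_lower_of_chrom_cds, 30)
})

test_that("chi-square statistic matches direct summation and known values", {
  r <- chi_square_bias(50, 50)
  expect_equal(r$chi2_stat, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, "none")

  r <- chi_square_bias(70, 30)
  expect_equal(r$chi2_stat, 16)                      # (20^2/50)*2
  expect_equal(r$df, 1)
  expect_equal(r$direction, "upper")

  r <- chi_square_bias(70, 30, "cds_proportional", background = c(700, 300))
  expect_equal(r$chi2_stat, 0)
  expect_equal(r$p_value, 1)

  set.seed(22)
  for (i in 1:200) {
    u <- sample(5:500, 1); l <- sample(5:500, 1)
    r <- suppressWarnings(chi_square_bias(u, l))
    e <- (u + l) / 2
    expect_equal(r$chi2_stat, brute_chi2(c(u, l), c(e, e)))
    expect_equal(r$p_value, pchisq(r$chi2_stat, 1, lower.tail = FALSE))
  }
})

test_that("chi-square errors on degenerate inputs and warns on small cells", {
  expect_error(chi_square_bias(0, 0), "undefined|zero")
  expect_error(chi_square_bias(3, 1, "cds_proportional", background = c(1, 0)),
               "exact test")
  expect_warning(chi_square_bias(4, 3), "expected count < 5")
})

test_that("chi-square is invariant to swapping halves; direction flips", {
  r1 <- suppressWarnings(chi_square_bias(80, 20))
  r2 <- suppressWarnings(chi_square_bias(20, 80))
  expect_equal(r1$chi2_stat, r2$chi2_stat)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$direction, "upper")
  expect_equal(r2$direction, "lower")
})

test_that("Bonferroni adjustment is min(1, m*p), monotone and order-preserving", {
  expect_equal(bonferroni(0.01), 0.01)               # m = 1
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(rep(0.9, 10))[1], 1)       # capped
  set.seed(23)
  p <- runif(50) / 100            # small enough that the cap never binds
  adj <- bonferroni(p)
  expect_true(all(adj >= p))
  expect_equal(adj, pmin(1, 50 * p))
  expect_equal(order(adj), order(p))
  expect_error(bonferroni(c(0.5, 1.2)))
})

test_that("bias_scan adjusts over the scan family and flags directions", {
  tab <- data.frame(genome_id = "G1", chrom_id = "c1",
                    category = c("core", "cloud"),
                    upper_count = c(300L, 100L), lower_count = c(100L, 300L),
                    pct_upper_of_chrom_cds = NA, pct_lower_of_chrom_cds = NA,
                    stringsAsFactors = FALSE)
  sc <- bias_scan(tab)
  expect_equal(sc$p_adj, pmin(1, 2 * sc$p))
  expect_true(all(sc$significant))
  expect_equal(sc$direction, c("upper", "lower"))
  # single test: adjusted equals raw
  sc1 <- bias_scan(tab[1, ])
  expect_equal(sc1$p_adj, sc1$p)
})

test_that("cds_proportional null uses the chromosome-wide upper:lower ratio", {
  tab <- data.frame(genome_id = "G1", chrom_id = "c1",
                    category = c("core", "cloud"),
                    upper_count = c(140L, 560L), lower_count = c(60L, 240L),
                    pct_upper_of_chrom_cds = NA, pct_lower_of_chrom_cds = NA,
                    stringsAsFactors = FALSE)
  # both categories split 70:30, the chromosome-wide ratio -> no signal
  sc <- bias_scan(tab, expected_mode = "cds_proportional")
  expect_equal(sc$chi2, c(0, 0))
  expect_false(any(sc$significant))
})
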