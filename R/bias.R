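#' @title Positional bias of pangene categories
#' @description Counts pangene categories per chromosome half, summarises
#'   them as percent of total CDS per chromosome, and tests each
#'   (genome, chromosome, category) cell for non-random distribution between
#'   the ori-proximal ("upper") and ter-proximal ("lower") halves with a
#'   1-df chi-square goodness-of-fit test, Bonferroni-corrected over the scan.
#' @name positional_bias
NULL

#' Per-half category counts and percentages
#'
#' @param loci gene loci from [locate_genes()] with `half` and `category`.
#' @return data.frame keyed by (`genome_id`, `chrom_id`, `category`) with
#'   `upper_count`, `lower_count` and the two halves as percent of that
#'   chromosome's total CDS. Percentages over all categories and halves sum
#'   to 100 per chromosome.
#' @export
distribution_counts <- function(loci) {
  key <- interaction(loci$genome_id, loci$chrom_id, loci$category,
                     drop = TRUE, sep = "\r")
  up <- tapply(loci$half == "upper", key, sum)
  lo <- tapply(loci$half == "lower", key, sum)
  parts <- do.call(rbind, strsplit(names(up), "\r", fixed = TRUE))
  out <- data.frame(genome_id = parts[, 1], chrom_id = parts[, 2],
                    category = parts[, 3],
                    upper_count = as.integer(up), lower_count = as.integer(lo),
                    stringsAsFactors = FALSE)
  chrom_tot <- tapply(rep(1L, nrow(loci)),
                      interaction(loci$genome_id, loci$chrom_id,
                                  drop = TRUE, sep = "\r"), sum)
  tot <- chrom_tot[paste(out$genome_id, out$chrom_id, sep = "\r")]
  out$pct_upper_of_chrom_cds <- 100 * out$upper_count / as.numeric(tot)
  out$pct_lower_of_chrom_cds <- 100 * out$lower_count / as.numeric(tot)
  out <- out[order(out$genome_id, out$chrom_id, out$category), ]
  rownames(out) <- NULL
  out
}

#' Chi-square test of upper vs lower half counts
#'
#' 1-df goodness-of-fit test of the observed (upper, lower) split against a
#' null that is either `uniform` (equal halves, E = n/2 each — the halves are
#' equal arcs by construction) or `cds_proportional` (expected split follows
#' the chromosome's overall upper:lower CDS ratio, for when gene density
#' itself is biased). No continuity correction, matching `chisq.test()` on a
#' two-cell table.
#'
#' @param upper,lower observed counts (their sum must be >= 1).
#' @param expected_mode `"uniform"` or `"cds_proportional"`.
#' @param background numeric length-2 `(upper_total, lower_total)` required
#'   for `cds_proportional`.
#' @return List with `chi2_stat`, `df`, `p_value`, `expected_upper`,
#'   `expected_lower`, `direction` (`"upper"`, `"lower"` or `"none"`).
#' @export
chi_square_bias <- function(upper, lower,
                            expected_mode = c("uniform", "cds_proportional"),
                            background = NULL) {
  expected_mode <- match.arg(expected_mode)
  n <- upper + lower
  if (n < 1) stop("both counts zero: test undefined")
  p <- if (expected_mode == "uniform") c(0.5, 0.5) else {
    if (is.null(background) || length(background) != 2)
      stop("cds_proportional requires background = c(upper_total, lower_total)")
    background / sum(background)
  }
  if (any(p * n == 0))
    stop("an expected count is zero; use an exact test instead")
  if (any(p * n < 5))
    warning("expected count < 5: chi-square approximation may be poor")
  ht <- suppressWarnings(stats::chisq.test(c(upper, lower), p = p))
  direction <- if (upper > n * p[1]) "upper" else if (upper < n * p[1]) "lower" else "none"
  list(chi2_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       expected_upper = n * p[1], expected_lower = n * p[2],
       direction = direction)
}

#' Bonferroni adjustment
#'
#' Each p-value is mapped to `min(1, m * p)` with `m` the family size
#' (the number of p-values supplied), via `p.adjust()`.
#'
#' @param p_values numeric vector in \\[0, 1\\].
#' @return Adjusted p-values, same length.
#' @export
bonferroni <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Scan all (genome, chromosome, category) cells for half bias
#'
#' Runs [chi_square_bias()] on every row of a [distribution_counts()] table
#' and Bonferroni-corrects over the scan. The correction family defaults to
#' all tests executed in the scan (the most conservative defensible family);
#' `family = "per_chromosome_set"` corrects within each (genome, chromosome)
#' set instead.
#'
#' @param table a [distribution_counts()] data.frame.
#' @param alpha significance level for the `significant` flag; default 0.05.
#' @param expected_mode,background passed to [chi_square_bias()];
#'   `cds_proportional` derives its background from the table itself.
#' @param family `"global"` (default) or `"per_chromosome_set"`.
#' @return `table` with columns `chi2`, `df`, `p`, `p_adj`,
#'   `expected_upper`, `expected_lower`, `direction`, `significant` added.
#'   Cells with zero genes are skipped (dropped from the scan).
#' @export
bias_scan <- function(table, alpha = 0.05,
                      expected_mode = c("uniform", "cds_proportional"),
                      family = c("global", "per_chromosome_set")) {
  expected_mode <- match.arg(expected_mode)
  family <- match.arg(family)
  table <- table[table$upper_count + table$lower_count >= 1, , drop = FALSE]
  res <- lapply(seq_len(nrow(table)), function(i) {
    bg <- if (expected_mode == "cds_proportional") {
      same <- table$genome_id == table$genome_id[i] &
        table$chrom_id == table$chrom_id[i]
      c(sum(table$upper_count[same]), sum(table$lower_count[same]))
    } else NULL
    chi_square_bias(table$upper_count[i], table$lower_count[i],
                    expected_mode, bg)
  })
  table$chi2 <- vapply(res, `[[`, 0, "chi2_stat")
  table$df <- vapply(res, `[[`, 0, "df")
  table$p <- vapply(res, `[[`, 0, "p_value")
  table$expected_upper <- vapply(res, `[[`, 0, "expected_upper")
  table$expected_lower <- vapply(res, `[[`, 0, "expected_lower")
  table$direction <- vapply(res, `[[`, "", "direction")
  if (family == "global") {
    table$p_adj <- bonferroni(table$p)
  } else {
    grp <- interaction(table$genome_id, table$chrom_id, drop = TRUE)
    table$p_adj <- stats::ave(table$p, grp, FUN = bonferroni)
  }
  table$significant <- table$p_adj <= alpha
  rownames(table) <- NULL
  table
}
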