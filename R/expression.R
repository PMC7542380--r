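#' @title Expression gradients along the ori-ter axis
#' @description RPKM computation from per-CDS read counts, log2-ratio-to-
#'   median global expression maps, a sliding-window trend over gene order
#'   (default window 200 data points, wrapping across ori on the circular
#'   chromosome), per-category upper/lower quartile tables and unpaired
#'   Wilcoxon rank tests of upper vs lower expression.
#' @name expression_gradient
NULL

#' Compute RPKM for every gene
#'
#' RPKM = read_count / ((length_bp/1000) * (total_mapped/1e6)), with
#' total_mapped the sum of read counts over all CDS of the genome (both
#' chromosomes): counts, not raw library size, are the pipeline's input, and
#' the two denominators are monotone-equivalent for within-sample
#' comparisons. Genes without a count row get count 0.
#'
#' @param counts data.frame with `gene_id`, `read_count` (e.g. from
#'   [read_counts()]); replicate tables may be pre-summed with
#'   [sum_replicates()].
#' @param loci gene loci from [locate_genes()] (lengths are taken from the
#'   coordinates).
#' @return An `expression_profile`: list with `genes` (data.frame `gene_id`,
#'   `read_count`, `length_bp`, `rpkm` plus the locus columns),
#'   `total_mapped` and `median_rpkm`.
#' @export
compute_rpkm <- function(counts, loci) {
  rc <- counts$read_count[match(loci$gene_id, counts$gene_id)]
  rc[is.na(rc)] <- 0
  total <- sum(counts$read_count)
  if (total == 0) stop("total mapped reads is zero")
  len <- gene_length(loci)
  rpkm <- rc / ((len / 1000) * (total / 1e6))
  genes <- cbind(loci,
                 data.frame(read_count = rc, length_bp = len, rpkm = rpkm))
  rownames(genes) <- NULL
  structure(list(genes = genes, total_mapped = total,
                 median_rpkm = stats::median(rpkm)),
            class = "expression_profile")
}

gene_length <- function(loci) {
  len <- loci$end_bp - loci$start_bp
  wrap <- len <= 0
  if (any(wrap)) {
    # wrapped genes: length measured around the circle; needs chrom length,
    # recoverable from midpoint arithmetic only if caller keeps it -- require
    # positive span instead.
    stop("wrapped gene records must be resolved to a positive span before RPKM")
  }
  len
}

#' Sum replicate count tables per gene
#'
#' @param count_list list of count data.frames (`gene_id`, `read_count`).
#' @return One combined count data.frame.
#' @export
sum_replicates <- function(count_list) {
  all <- do.call(rbind, count_list)
  agg <- tapply(all$read_count, all$gene_id, sum)
  data.frame(gene_id = names(agg), read_count = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' log2 ratio of each gene's RPKM to the median RPKM
#'
#' The global expression map statistic: `log2(rpkm / median)`. Zero-RPKM
#' genes cannot be logged; they are imputed at epsilon = half the smallest
#' nonzero RPKM in the scope and flagged (`imputed = TRUE`) so downstream
#' slope fits can exclude them while quartile tables keep the zeros.
#'
#' @param profile an `expression_profile` from [compute_rpkm()].
#' @param median_scope `"genome"` (default; one median over both
#'   chromosomes, one map centre per dataset) or `"per_chromosome"`.
#' @return The profile with `log2_ratio`, `imputed` columns added to
#'   `$genes`, and `median_rpkm` set per the scope.
#' @export
log2_ratio_map <- function(profile, median_scope = c("genome", "per_chromosome")) {
  median_scope <- match.arg(median_scope)
  g <- profile$genes
  scope <- if (median_scope == "genome") rep("all", nrow(g)) else g$chrom_id
  g$log2_ratio <- NA_real_
  g$imputed <- FALSE
  for (s in unique(scope)) {
    i <- scope == s
    med <- stats::median(g$rpkm[i])
    if (med <= 0) stop("median RPKM is zero in scope ", s)
    nz <- g$rpkm[i][g$rpkm[i] > 0]
    eps <- min(nz) / 2
    x <- g$rpkm[i]
    imput <- x == 0
    x[imput] <- eps
    g$log2_ratio[i] <- log2(x / med)
    g$imputed[i] <- imput
  }
  profile$genes <- g
  profile$median_rpkm <- stats::median(g$rpkm)
  profile
}

#' Centered sliding-window mean over gene order
#'
#' Smooths a per-gene signal (typically the log2 RPKM ratio of genes sorted
#' by recentred position within a chromosome) with a moving average over a
#' window of `window` data points, by default wrapping across the origin
#' (`circular = TRUE`) since the chromosome is a circle. Returns one smoothed
#' value per input position. For even windows the extra point sits forward in
#' gene order (the convention of `stats::filter()`).
#'
#' @param x numeric vector, genes in chromosomal order.
#' @param window window size in data points; default 200.
#' @param circular wrap across the ends; default `TRUE`.
#' @return Numeric vector, same length as `x`.
#' @export
sliding_trend <- function(x, window = 200L, circular = TRUE) {
  n <- length(x)
  if (window > n)
    stop("window (", window, ") exceeds number of genes (", n,
         "); choose a smaller window")
  if (window == 1L) return(x)
  if (circular) {
    as.numeric(stats::filter(x, rep(1 / window, window), sides = 2,
                             circular = TRUE))
  } else {
    as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  }
}

#' Trend table for an expression profile
#'
#' Orders genes by recentred position within each chromosome and attaches
#' the sliding-window mean of the log2 ratio.
#'
#' @param profile profile with `log2_ratio` (see [log2_ratio_map()]).
#' @param window,circular passed to [sliding_trend()].
#' @return data.frame `gene_id`, `chrom_id`, `recentred_bp`, `log2_ratio`,
#'   `trend`, ordered by chromosome then position.
#' @export
expression_trend <- function(profile, window = 200L, circular = TRUE) {
  g <- profile$genes
  out <- lapply(split(g, g$chrom_id), function(gc) {
    gc <- gc[order(gc$recentred_bp, gc$gene_id), , drop = FALSE]
    gc$trend <- sliding_trend(gc$log2_ratio, min(window, nrow(gc)), circular)
    gc[, c("gene_id", "chrom_id", "recentred_bp", "log2_ratio", "trend")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quartile table of RPKM per category and chromosome half
#'
#' The layout of a per-condition expression comparison: for each pangene
#' category and half, the first quartile Q1, median Q2, third quartile Q3 and
#' maximum of the RPKM values, with quantiles by linear interpolation between
#' order statistics at positions `(n-1)*q`. Zero-RPKM genes are kept.
#'
#' @param profile an `expression_profile`.
#' @param condition label stamped on every row.
#' @param chrom restrict to one chromosome id (default: the chromosome with
#'   most genes — the large chromosome).
#' @return data.frame `condition`, `category`, `half`, `Q1`, `Q2`, `Q3`,
#'   `Max`, `n_genes`; empty cells keep `n_genes = 0` and `NA` quartiles.
#' @export
quartile_table <- function(profile, condition = "condition", chrom = NULL) {
  g <- profile$genes
  if (is.null(chrom))
    chrom <- names(which.max(table(g$chrom_id)))
  g <- g[g$chrom_id == chrom, , drop = FALSE]
  cats <- intersect(c("core", "softcore", "shell", "cloud"),
                    unique(g$category))
  rows <- list()
  for (half in c("upper", "lower")) for (cat in cats) {
    x <- g$rpkm[g$half == half & g$category == cat]
    if (length(x) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        condition = condition, category = cat, half = half,
        Q1 = NA_real_, Q2 = NA_real_, Q3 = NA_real_, Max = NA_real_,
        n_genes = 0L, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        condition = condition, category = cat, half = half,
        Q1 = q[1], Q2 = q[2], Q3 = q[3], Max = max(x),
        n_genes = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unpaired Wilcoxon rank test of upper vs lower expression
#'
#' Two-sample unpaired rank-sum comparison (the procedure R's `wilcox.test()`
#' performs with `paired` unset — the upper- and lower-half genes are
#' different genes, so pairing is undefined), two-sided; exact enumeration
#' for small samples without ties, normal approximation with tie correction
#' otherwise.
#'
#' @param upper_rpkms,lower_rpkms numeric vectors, both non-empty.
#' @return List with `statistic` (rank-sum W of the upper group), `p_value`,
#'   `median_upper`, `median_lower`.
#' @export
rank_test_upper_vs_lower <- function(upper_rpkms, lower_rpkms) {
  if (length(upper_rpkms) == 0 || length(lower_rpkms) == 0)
    stop("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(upper_rpkms, lower_rpkms,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_upper = stats::median(upper_rpkms),
       median_lower = stats::median(lower_rpkms))
}

#' Rank-test scan over pangene categories
#'
#' Runs [rank_test_upper_vs_lower()] for every category on one chromosome
#' and Bonferroni-corrects over the scan.
#'
#' @param profile an `expression_profile`.
#' @param condition condition label.
#' @param chrom chromosome id (default as in [quartile_table()]).
#' @param alpha significance level; default 0.05.
#' @return data.frame `condition`, `category`, `statistic`, `p_value`,
#'   `p_adjusted`, `median_upper`, `median_lower`, `significant`.
#' @export
expression_rank_scan <- function(profile, condition = "condition",
                                 chrom = NULL, alpha = 0.05) {
  g <- profile$genes
  if (is.null(chrom))
    chrom <- names(which.max(table(g$chrom_id)))
  g <- g[g$chrom_id == chrom, , drop = FALSE]
  cats <- intersect(c("core", "softcore", "shell", "cloud"),
                    unique(g$category))
  rows <- lapply(cats, function(cat) {
    up <- g$rpkm[g$half == "upper" & g$category == cat]
    lo <- g$rpkm[g$half == "lower" & g$category == cat]
    if (length(up) == 0 || length(lo) == 0) return(NULL)
    r <- rank_test_upper_vs_lower(up, lo)
    data.frame(condition = condition, category = cat,
               statistic = r$statistic, p_value = r$p_value,
               median_upper = r$median_upper, median_lower = r$median_lower,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_value)
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}

#' Slope of log2(RPKM) against relative distance to ori
#'
#' Ordinary least squares of `log2(rpkm)` on `rel_dist` (`u`, 0 at ori, 1 at
#' ter), excluding imputed zero-count genes. Under a multifork gene-dosage
#' model with copy number `2^(k * (1 - u))` the expected slope is `-k`.
#'
#' @param profile profile with `log2_ratio`/`imputed` (see
#'   [log2_ratio_map()]).
#' @param chrom restrict to one chromosome (default: largest gene count).
#' @return List with `slope`, `se`, `p_value`, `n`.
#' @export
dosage_slope <- function(profile, chrom = NULL) {
  g <- profile$genes
  if (is.null(chrom))
    chrom <- names(which.max(table(g$chrom_id)))
  g <- g[g$chrom_id == chrom & !g$imputed, , drop = FALSE]
  fit <- stats::lm(log2(rpkm) ~ rel_dist, data = g)
  co <- summary(fit)$coefficients
  list(slope = co["rel_dist", "Estimate"], se = co["rel_dist", "Std. Error"],
       p_value = co["rel_dist", "Pr(>|t|)"], n = nrow(g))
}
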