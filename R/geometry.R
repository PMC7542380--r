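#' Midpoint of a gene on a circular chromosome
#'
#' Computes the integer midpoint of a CDS along a circle of length `L`.
#' Genes that wrap the linear origin of the sequence are encoded as
#' `end_bp <= start_bp` and are unwrapped before averaging, so the midpoint
#' always lies in `[0, L)`.
#'
#' @param start_bp,end_bp 0-based half-open coordinates. `end_bp <= start_bp`
#'   marks a gene spanning the end of the linear sequence.
#' @param L chromosome length in bp (positive).
#' @return Integer midpoint position(s) in `[0, L)`.
#' @examples
#' gene_midpoint(100, 300, 1000)  # 200
#' gene_midpoint(900, 100, 1000)  # 0 (wraps)
#' @export
gene_midpoint <- function(start_bp, end_bp, L) {
  if (any(L <= 0)) stop("chromosome length L must be positive")
  wrap <- end_bp <= start_bp
  end_eff <- ifelse(wrap, end_bp + L, end_bp)
  floor((start_bp + end_eff) / 2) %% L
}

#' Circular distance between two positions
#'
#' Shortest arc distance on a circle of length `L`; symmetric and bounded by
#' `L / 2`. This is the gene-to-ori distance used throughout the positional
#' analysis.
#'
#' @param pos,ori positions in `[0, L)`.
#' @param L chromosome length in bp.
#' @return Distance(s) in `[0, L/2]`.
#' @export
circular_distance <- function(pos, ori, L) {
  d <- abs(pos - ori) %% L
  pmin(d, L - d)
}

#' Recentre a position on the replication origin
#'
#' Signed offset from `ori` with clockwise (increasing coordinate) positive,
#' in `(-L/2, L/2]`. `recentre(ori) == 0` and `abs(recentre(p))` equals
#' [circular_distance()]. Used to centre expression maps and Circos plots at
#' the origin of replication.
#'
#' @inheritParams circular_distance
#' @return Signed offset(s) in `(-L/2, L/2]`.
#' @export
recentre <- function(pos, ori, L) {
  r <- (pos - ori) %% L
  ifelse(r > L / 2, r - L, r)
}

#' Assign a position to the upper (ori-proximal) or lower (ter-proximal) half
#'
#' With the default antipodal terminus the chromosome is split into two equal
#' arcs: a position is "upper" iff its distance to ori is strictly less than
#' `L / 4` (a tie at exactly `L / 4` goes to "lower"). With an explicit `ter_bp`
#' the two replichore arcs may be unequal; a position is then "upper" iff it
#' lies in the half of its replichore arc nearer ori (per-arc midpoint rule,
#' ties again to "lower").
#'
#' @param dist_to_ori_bp circular distance(s) to ori (used for the equal-arc
#'   rule; ignored when `ter_bp` is given, where `pos` is required instead).
#' @param L chromosome length in bp.
#' @param ter_bp optional explicit terminus position.
#' @param pos,ori raw position and ori, required when `ter_bp` is supplied.
#' @return Character vector of `"upper"` / `"lower"`.
#' @export
assign_half <- function(dist_to_ori_bp, L, ter_bp = NULL, pos = NULL, ori = NULL) {
  if (is.null(ter_bp)) {
    return(ifelse(dist_to_ori_bp < L / 4, "upper", "lower"))
  }
  if (is.null(pos) || is.null(ori))
    stop("explicit ter_bp requires pos and ori")
  a1 <- (ter_bp - ori) %% L          # clockwise arc ori -> ter
  a2 <- L - a1                       # counter-clockwise arc
  dcw <- (pos - ori) %% L
  on_arc1 <- dcw <= a1
  upper <- ifelse(on_arc1, dcw < a1 / 2, (L - dcw) < a2 / 2)
  ifelse(upper, "upper", "lower")
}

#' Locate genes on their chromosomes
#'
#' Joins gene records with chromosome definitions (and, optionally, cluster
#' category assignments) and derives for every gene: its midpoint, circular
#' distance to ori, relative distance `u = 2 d / L` (0 at ori, 1 at ter), the
#' ori-recentred signed coordinate, and the upper/lower half. Strand is
#' carried through but plays no role in any positional statistic.
#'
#' @param genes data.frame of gene records (`gene_id`, `genome_id`, `chrom_id`,
#'   `start_bp`, `end_bp`, `strand`, optional `cluster_id`).
#' @param chrom_defs data.frame of chromosome definitions (`chrom_id`,
#'   `length_bp`, `ori_bp`, optional `ter_bp`).
#' @param assignments optional result of [classify_all()] (or its
#'   `$assignments` data.frame) used to attach pangene categories via
#'   [attach_categories()].
#' @param position_rule `"midpoint"` (default) or `"start"`: which coordinate
#'   represents the gene. The source data do not dictate a convention;
#'   midpoint is the default because it is symmetric under strand and wrap.
#' @param use_ter use an explicit terminus from `chrom_defs$ter_bp` when
#'   present (unequal replichores); default `FALSE` = antipodal ter.
#' @param orphan_policy passed to [attach_categories()] when `assignments`
#'   is supplied.
#' @return data.frame of gene loci with columns `gene_id`, `genome_id`,
#'   `chrom_id`, `start_bp`, `end_bp`, `strand`, `cluster_id`, `category`,
#'   `midpoint_bp`, `dist_to_ori_bp`, `rel_dist`, `recentred_bp`, `half`.
#' @export
locate_genes <- function(genes, chrom_defs, assignments = NULL,
                         position_rule = c("midpoint", "start"),
                         use_ter = FALSE, orphan_policy = "strict") {
  position_rule <- match.arg(position_rule)
  if (!is.null(assignments))
    genes <- attach_categories(genes, assignments, policy = orphan_policy)
  if (is.null(genes$category)) genes$category <- NA_character_
  if (is.null(genes$cluster_id)) genes$cluster_id <- NA_character_

  missing_chrom <- setdiff(unique(genes$chrom_id), chrom_defs$chrom_id)
  if (length(missing_chrom) > 0)
    stop("no ChromosomeDef for chromosome(s): ",
         paste(missing_chrom, collapse = ", "))

  idx <- match(genes$chrom_id, chrom_defs$chrom_id)
  L <- chrom_defs$length_bp[idx]
  ori <- chrom_defs$ori_bp[idx]
  ter <- if (!is.null(chrom_defs$ter_bp)) chrom_defs$ter_bp[idx] else rep(NA_real_, length(idx))

  pos <- if (position_rule == "midpoint")
    gene_midpoint(genes$start_bp, genes$end_bp, L) else genes$start_bp %% L
  d <- circular_distance(pos, ori, L)

  half <- character(nrow(genes))
  has_ter <- use_ter & !is.na(ter)
  half[!has_ter] <- assign_half(d[!has_ter], L[!has_ter])
  if (any(has_ter))
    half[has_ter] <- assign_half(d[has_ter], L[has_ter], ter_bp = ter[has_ter],
                                 pos = pos[has_ter], ori = ori[has_ter])

  out <- data.frame(
    gene_id = genes$gene_id, genome_id = genes$genome_id,
    chrom_id = genes$chrom_id, start_bp = genes$start_bp,
    end_bp = genes$end_bp, strand = genes$strand,
    cluster_id = genes$cluster_id, category = genes$category,
    midpoint_bp = pos, dist_to_ori_bp = d, rel_dist = 2 * d / L,
    recentred_bp = recentre(pos, ori, L), half = half,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
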