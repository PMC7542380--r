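#' @title Pangene occupancy and category classification
#' @description Clusters of orthologous genes are classified by occupancy —
#'   the number of genomes encoding at least one member — into the four
#'   pangene categories: core (all N genomes), softcore (at least
#'   `floor(softcore_fraction * N)` genomes), shell (intermediate) and cloud
#'   (at most `cloud_max` genomes). With N = 124 genomes and the defaults
#'   (softcore fraction 0.95, cloud max 2) the boundaries are core = 124,
#'   softcore >= 117, shell 3..116, cloud <= 2.
#' @name pangene_classification
NULL

#' Category thresholds for a pangenome of N genomes
#'
#' @param n_genomes number of genomes N (>= 1).
#' @param softcore_fraction fraction of genomes required for softcore
#'   membership, in (0, 1]; default 0.95 (the common clustering-tool
#'   convention). The softcore minimum is `floor(softcore_fraction * N)`.
#' @param cloud_max maximum occupancy of a cloud cluster; default 2.
#' @return List with `n_genomes`, `softcore_fraction`, `cloud_max` and the
#'   derived `softcore_min`.
#' @export
category_thresholds <- function(n_genomes, softcore_fraction = 0.95, cloud_max = 2L) {
  stopifnot(n_genomes >= 1, softcore_fraction > 0, softcore_fraction <= 1)
  sc_min <- softcore_threshold(n_genomes, softcore_fraction)
  if (!(cloud_max < 3 && 3 <= sc_min && sc_min <= n_genomes))
    stop("infeasible thresholds: need cloud_max < 3 <= softcore_min <= N ",
         "(got softcore_min = ", sc_min, ", N = ", n_genomes, ")")
  list(n_genomes = as.integer(n_genomes),
       softcore_fraction = softcore_fraction,
       cloud_max = as.integer(cloud_max),
       softcore_min = as.integer(sc_min))
}

#' Minimum occupancy for softcore membership
#'
#' `floor(softcore_fraction * N)`; with N = 124 and fraction 0.95 this is 117.
#'
#' @inheritParams category_thresholds
#' @return Integer threshold.
#' @export
softcore_threshold <- function(n_genomes, softcore_fraction = 0.95) {
  stopifnot(n_genomes >= 1)
  as.integer(floor(softcore_fraction * n_genomes))
}

#' Occupancy of a cluster
#'
#' Number of genomes with at least one member of the cluster; paralogs
#' (cell values > 1) count once.
#'
#' @param matrix a `pangenome_matrix` (see [read_pangenome_matrix()]) or a
#'   plain cluster-by-genome integer matrix with cluster row names.
#' @param cluster_id cluster identifier(s); default all clusters.
#' @return Named integer vector of occupancies.
#' @export
occupancy <- function(matrix, cluster_id = NULL) {
  m <- unclass_matrix(matrix)
  if (is.null(cluster_id)) cluster_id <- rownames(m)
  unknown <- setdiff(cluster_id, rownames(m))
  if (length(unknown) > 0)
    stop("unknown cluster(s): ", paste(unknown, collapse = ", "))
  occ <- rowSums(m[cluster_id, , drop = FALSE] >= 1L)
  storage.mode(occ) <- "integer"
  occ
}

unclass_matrix <- function(matrix) {
  if (inherits(matrix, "pangenome_matrix")) matrix$counts else as.matrix(matrix)
}

#' Classify an occupancy value into a pangene category
#'
#' Returns both the nested view (softcore includes core, the clustering-tool
#' convention) and the exclusive view in which the four categories partition
#' the clusters: core iff occupancy = N; softcore (nested) iff occupancy >=
#' softcore_min; shell iff cloud_max < occupancy < softcore_min; cloud iff
#' occupancy <= cloud_max.
#'
#' @param occ occupancy value(s) in `[1, N]`.
#' @param thresholds a [category_thresholds()] list.
#' @return data.frame with columns `occupancy`, `category_nested`,
#'   `category_exclusive`.
#' @export
classify_cluster <- function(occ, thresholds) {
  N <- thresholds$n_genomes
  if (any(occ < 1 | occ > N))
    stop("occupancy out of range [1, ", N, "]")
  nested <- ifelse(occ >= thresholds$softcore_min, "softcore",
            ifelse(occ > thresholds$cloud_max, "shell", "cloud"))
  exclusive <- ifelse(occ == N, "core", nested)
  data.frame(occupancy = as.integer(occ),
             category_nested = nested,
             category_exclusive = exclusive,
             stringsAsFactors = FALSE)
}

#' Classify every cluster of a pangenome matrix
#'
#' @param matrix a `pangenome_matrix` or cluster-by-genome count matrix.
#' @param thresholds a [category_thresholds()] list; default thresholds for
#'   the matrix's genome count.
#' @return List with `assignments` (data.frame `cluster_id`, `occupancy`,
#'   `category_nested`, `category_exclusive`) and `summary` (per-category
#'   counts and percentages in both views; exclusive categories partition the
#'   clusters, so their counts and percentages sum to the total and 100).
#' @export
classify_all <- function(matrix, thresholds = NULL) {
  m <- unclass_matrix(matrix)
  if (is.null(thresholds)) thresholds <- category_thresholds(ncol(m))
  occ <- occupancy(m)
  cls <- classify_cluster(occ, thresholds)
  assignments <- cbind(data.frame(cluster_id = rownames(m),
                                  stringsAsFactors = FALSE), cls)
  rownames(assignments) <- NULL

  cats <- c("core", "softcore", "shell", "cloud")
  n_total <- nrow(assignments)
  n_excl <- vapply(cats, function(k) sum(assignments$category_exclusive == k), 0L)
  n_nest <- vapply(cats, function(k)
    if (k == "core") sum(assignments$category_exclusive == "core")
    else sum(assignments$category_nested == k), 0L)
  summary <- data.frame(
    category = cats,
    count_exclusive = as.integer(n_excl),
    pct_exclusive = 100 * n_excl / n_total,
    count_nested = as.integer(n_nest),
    pct_nested = 100 * n_nest / n_total,
    stringsAsFactors = FALSE
  )
  list(assignments = assignments, summary = summary,
       thresholds = thresholds, n_clusters = n_total)
}

#' Attach pangene categories to gene records
#'
#' Joins genes to cluster category assignments on `cluster_id`.
#'
#' @param genes data.frame of gene records with a `cluster_id` column.
#' @param assignments a [classify_all()] result or its `$assignments`
#'   data.frame.
#' @param policy what to do with orphan genes whose cluster is absent from the
#'   assignments: `"strict"` (error listing gene ids), `"drop"` (exclude with
#'   a warning) or `"unassigned"` (keep, category `"unassigned"`).
#' @param view `"exclusive"` (default; the four categories partition the
#'   genes, as in the distribution and expression reporting) or `"nested"`.
#' @return `genes` with a `category` column added.
#' @export
attach_categories <- function(genes, assignments,
                              policy = c("strict", "drop", "unassigned"),
                              view = c("exclusive", "nested")) {
  policy <- match.arg(policy)
  view <- match.arg(view)
  if (is.list(assignments) && !is.data.frame(assignments))
    assignments <- assignments$assignments
  col <- paste0("category_", view)
  idx <- match(genes$cluster_id, assignments$cluster_id)
  orphan <- is.na(idx)
  if (any(orphan)) {
    ids <- genes$gene_id[orphan]
    if (policy == "strict")
      stop("orphan gene(s) with no cluster assignment: ",
           paste(utils::head(ids, 10), collapse = ", "),
           if (length(ids) > 10) ", ..." else "")
    if (policy == "drop") {
      warning(length(ids), " orphan gene(s) dropped")
      genes <- genes[!orphan, , drop = FALSE]
      idx <- idx[!orphan]
    }
  }
  genes$category <- assignments[[col]][idx]
  if (policy == "unassigned")
    genes$category[is.na(genes$category)] <- "unassigned"
  rownames(genes) <- NULL
  genes
}
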