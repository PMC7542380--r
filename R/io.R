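#' @title External formats
#' @description Readers and writers for every external representation the
#'   pipeline touches: GFF3 gene coordinates, tab-delimited pangenome
#'   matrices, ori-position CSV tables, per-CDS count tables, Circos
#'   karyotype/track files and TSV report tables. Internal coordinates are
#'   0-based half-open throughout; the GFF3 boundary converts from/to the
#'   1-based inclusive convention.
#' @name io_formats
NULL

#' Read CDS gene records from a GFF3 file
#'
#' Parses a GFF3 file via rtracklayer, keeps CDS features only, and converts
#' 1-based inclusive coordinates to the internal 0-based half-open convention.
#' Chromosome lengths come from `##sequence-region` pragmas or from a
#' companion `lengths` table. GenBank input is supported only via prior
#' conversion to GFF3 (a single source of coordinate truth).
#'
#' @param path GFF3 file.
#' @param genome_id genome identifier stamped on every record.
#' @param lengths optional data.frame (`chrom_id`, `length_bp`) overriding or
#'   supplementing sequence-region pragmas.
#' @return List with `genes` (data.frame: `gene_id`, `genome_id`, `chrom_id`,
#'   `start_bp`, `end_bp`, `strand`, `cluster_id`) and `chroms` (data.frame:
#'   `chrom_id`, `length_bp`).
#' @export
read_gff <- function(path, genome_id, lengths = NULL) {
  validate_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  meta <- S4Vectors::mcols(gr)
  ids <- if (!is.null(meta$ID)) as.character(meta$ID) else
    paste0(genome_id, "_cds", seq_along(gr))
  cluster <- if (!is.null(meta$cluster_id)) as.character(meta$cluster_id)
             else rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = ids,
    genome_id = genome_id,
    chrom_id = as.character(GenomeInfoDb::seqnames(gr)),
    start_bp = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
    end_bp = GenomicRanges::end(gr),
    strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
    cluster_id = cluster,
    stringsAsFactors = FALSE
  )
  chroms <- read_sequence_regions(path)
  if (!is.null(lengths)) {
    keep <- !(chroms$chrom_id %in% lengths$chrom_id)
    chroms <- rbind(chroms[keep, , drop = FALSE],
                    data.frame(chrom_id = lengths$chrom_id,
                               length_bp = as.numeric(lengths$length_bp),
                               stringsAsFactors = FALSE))
  }
  chroms <- chroms[!is.na(chroms$length_bp), , drop = FALSE]
  unknown <- setdiff(genes$chrom_id, chroms$chrom_id)
  if (length(unknown) > 0)
    stop("CDS on chromosome(s) with unknown length: ",
         paste(unknown, collapse = ", "),
         " (add ##sequence-region pragmas or a lengths table)")
  bad <- genes$start_bp < 0 |
    genes$start_bp >= chroms$length_bp[match(genes$chrom_id, chroms$chrom_id)]
  if (any(bad))
    stop("CDS start outside chromosome: ",
         paste(genes$gene_id[bad], collapse = ", "))
  rownames(genes) <- NULL
  rownames(chroms) <- NULL
  list(genes = genes, chroms = chroms)
}

# Cheap structural validation so malformed lines fail with a line number
# (the GFF3 library reports parse problems without one).
validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1]]
    stop("malformed GFF line ", lineno, " in ", path,
         ": expected 9 tab-separated fields, found ", nfield[nfield != 9L][1])
  }
  invisible(TRUE)
}

# ##sequence-region <id> <start> <end> pragmas -> chromosome lengths
read_sequence_regions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prag <- grep("^##sequence-region\\s", lines, value = TRUE)
  if (length(prag) == 0)
    return(data.frame(chrom_id = character(0), length_bp = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(sub("^##sequence-region\\s+", "", prag), "\\s+")
  data.frame(chrom_id = vapply(parts, `[`, "", 1),
             length_bp = as.numeric(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Write gene records to a GFF3 file
#'
#' Inverse of [read_gff()]: 0-based half-open records become 1-based
#' inclusive CDS features with `##sequence-region` pragmas. Cluster ids are
#' stored in a `cluster_id` attribute. Written by hand (not via a library
#' exporter) so output is fully deterministic: identical inputs give
#' byte-identical files.
#'
#' @param genes,chroms as returned by [read_gff()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, chroms, path) {
  if (any(genes$end_bp <= genes$start_bp))
    stop("cannot emit wrapped CDS (end_bp <= start_bp) as GFF3")
  attrs <- paste0("ID=", genes$gene_id)
  has_cluster <- !is.null(genes$cluster_id) & !is.na(genes$cluster_id)
  attrs[has_cluster] <- paste0(attrs[has_cluster], ";cluster_id=",
                               genes$cluster_id[has_cluster])
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", chroms$chrom_id,
            as.integer(chroms$length_bp)),
    sprintf("%s\treplipan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
            genes$chrom_id, genes$start_bp + 1L, as.integer(genes$end_bp),
            genes$strand, attrs)
  ), path)
  invisible(path)
}

#' Read a cluster-by-genome pangenome matrix
#'
#' Reads the tab-delimited occupancy-count layout emitted by pangenome
#' clustering tools. Orientation (clusters as rows vs columns) is
#' auto-detected by matching labels against `genome_ids` when supplied;
#' `transpose = TRUE` forces a flip. Cells are non-negative integer member
#' counts (values > 1 are paralogs; occupancy counts them once).
#'
#' @param path tab-delimited file; first column holds row labels, header row
#'   holds column labels.
#' @param genome_ids optional character vector used to auto-detect
#'   orientation.
#' @param transpose force transposition of the file's layout.
#' @return A `pangenome_matrix`: list with `counts` (integer matrix, clusters
#'   x genomes), `cluster_ids`, `genome_ids`.
#' @export
read_pangenome_matrix <- function(path, genome_ids = NULL, transpose = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != floor(m)) || any(m < 0))
    stop("pangenome matrix cells must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- labs
  if (!is.null(genome_ids)) {
    row_hits <- mean(rownames(m) %in% genome_ids)
    col_hits <- mean(colnames(m) %in% genome_ids)
    if (row_hits > col_hits) m <- t(m)     # genomes were rows
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicated genome id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  pangenome_matrix(m)
}

#' Construct a pangenome_matrix from a cluster-by-genome count matrix
#'
#' @param counts integer matrix, clusters as rows, genomes as columns, with
#'   dimnames.
#' @return A `pangenome_matrix` object.
#' @export
pangenome_matrix <- function(counts) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  structure(list(counts = counts,
                 cluster_ids = rownames(counts),
                 genome_ids = colnames(counts)),
            class = "pangenome_matrix")
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat("pangenome_matrix:", nrow(x$counts), "clusters x",
      ncol(x$counts), "genomes\n")
  invisible(x)
}

#' Write a pangenome matrix as tab-delimited text
#'
#' @param matrix a `pangenome_matrix`.
#' @param path output file.
#' @param label header of the first (cluster id) column.
#' @return `path`, invisibly.
#' @export
write_pangenome_matrix <- function(matrix, path, label = "cluster_id") {
  m <- unclass_matrix(matrix)
  df <- data.frame(m, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m)), label), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome/ori definition table
#'
#' CSV with columns `chrom_id`, `length_bp`, `ori_bp` and optional `ter_bp`
#' (the layout of an origin-database export). Positions are 0-based.
#'
#' @param path CSV file.
#' @return data.frame of validated chromosome definitions; absent `ter_bp`
#'   is `NA`.
#' @export
read_ori_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chrom_id", "length_bp", "ori_bp")
  if (!all(need %in% names(tab)))
    stop("ori table must have columns: ", paste(need, collapse = ", "))
  if (!"ter_bp" %in% names(tab)) tab$ter_bp <- NA_real_
  tab$ter_bp[tab$ter_bp %in% ""] <- NA
  tab$ter_bp <- as.numeric(tab$ter_bp)
  validate_chrom_defs(tab)
  tab[, c("chrom_id", "length_bp", "ori_bp", "ter_bp")]
}

validate_chrom_defs <- function(defs) {
  with(defs, {
    if (any(length_bp <= 0)) stop("length_bp must be positive")
    if (any(ori_bp < 0 | ori_bp >= length_bp))
      stop("ori_bp out of range [0, length_bp) for: ",
           paste(chrom_id[ori_bp < 0 | ori_bp >= length_bp], collapse = ", "))
    bad_ter <- !is.na(ter_bp) & (ter_bp < 0 | ter_bp >= length_bp | ter_bp == ori_bp)
    if (any(bad_ter))
      stop("ter_bp invalid (out of range or equal to ori_bp) for: ",
           paste(chrom_id[bad_ter], collapse = ", "))
  })
  invisible(defs)
}

#' Write Circos karyotype and per-category track files
#'
#' Emits the plain-text Circos dialect: one karyotype file
#' (`chr - <id> <label> 0 <length> <color>` per chromosome), one two-column
#' interval track per pangene category (`<chrom> <start> <end>` per gene) and,
#' when `values` is supplied, an expression track
#' (`<chrom> <start> <end> <value>`). All coordinates are recentred so that
#' position 0 is the replication origin (plots centred at ori); an interval
#' crossing the wrap point is split in two.
#'
#' @param loci gene loci from [locate_genes()] (must carry `category`).
#' @param chrom_defs chromosome definitions.
#' @param out_dir output directory (created if needed).
#' @param values optional named numeric vector (names = gene ids) for the
#'   expression track, e.g. log2 RPKM ratios.
#' @param colors named character vector of per-category Circos colors.
#' @return Character vector of files written, invisibly.
#' @export
write_circos_tracks <- function(loci, chrom_defs, out_dir, values = NULL,
                                colors = c(core = "vdblue", softcore = "blue",
                                           shell = "orange", cloud = "vdred")) {
  if (any(is.na(loci$category)))
    stop("every gene needs a category before Circos export")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  kpath <- file.path(out_dir, "karyotype.txt")
  defs <- chrom_defs[order(chrom_defs$chrom_id), , drop = FALSE]
  writeLines(sprintf("chr - %s %s 0 %d grey", defs$chrom_id, defs$chrom_id,
                     as.integer(defs$length_bp)), kpath)
  files <- c(files, kpath)

  idx <- match(loci$chrom_id, chrom_defs$chrom_id)
  L <- chrom_defs$length_bp[idx]
  ori <- chrom_defs$ori_bp[idx]
  s <- (loci$start_bp - ori) %% L
  len <- (loci$end_bp - loci$start_bp) %% L
  len[len == 0] <- 1
  e <- s + len

  interval_lines <- function(keep, value = NULL) {
    ss <- s[keep]; ee <- e[keep]; ll <- L[keep]; ch <- loci$chrom_id[keep]
    vv <- if (is.null(value)) NULL else value[keep]
    out <- character(0)
    over <- ee > ll
    fmt <- function(c_, a, b, v)
      if (is.null(v)) sprintf("%s %d %d", c_, as.integer(a), as.integer(b))
      else sprintf("%s %d %d %s", c_, as.integer(a), as.integer(b),
                   formatC(v, format = "f", digits = 4))
    out <- c(out, fmt(ch[!over], ss[!over], ee[!over],
                      if (is.null(vv)) NULL else vv[!over]))
    if (any(over)) {   # wraps past the recentred end: split
      out <- c(out,
               fmt(ch[over], ss[over], ll[over],
                   if (is.null(vv)) NULL else vv[over]),
               fmt(ch[over], rep(0, sum(over)), ee[over] - ll[over],
                   if (is.null(vv)) NULL else vv[over]))
    }
    sort(out)
  }

  for (cat in sort(unique(loci$category))) {
    keep <- loci$category == cat
    tpath <- file.path(out_dir, paste0("track_", cat, ".txt"))
    writeLines(interval_lines(keep), tpath)
    files <- c(files, tpath)
  }
  if (!is.null(values)) {
    v <- values[loci$gene_id]
    keep <- !is.na(v)
    tpath <- file.path(out_dir, "track_expression.txt")
    writeLines(interval_lines(keep, value = unname(v)), tpath)
    files <- c(files, tpath)
  }
  invisible(files)
}

#' Read a two-column gene count table
#'
#' @param path TSV with columns `gene_id`, `count` (header optional when the
#'   first field is non-numeric).
#' @return data.frame with `gene_id`, `read_count`.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           header = FALSE, col.names = c("gene_id", "read_count"))
  if (is.na(suppressWarnings(as.numeric(tab$read_count[1]))))
    tab <- tab[-1, , drop = FALSE]   # header row
  tab$read_count <- as.numeric(tab$read_count)
  if (any(is.na(tab$read_count)) || any(tab$read_count < 0) ||
      any(tab$read_count != floor(tab$read_count)))
    stop("read counts must be non-negative integers")
  rownames(tab) <- NULL
  tab
}

#' Write a gene count table
#' @param counts data.frame with `gene_id`, `read_count`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts[, c("gene_id", "read_count")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write report tables as TSV
#'
#' Deterministic writer for the pipeline's result tables: fixed column order
#' (as given), floats at fixed 6-decimal precision, one file per logical
#' table. Identical inputs produce byte-identical files.
#'
#' @param tables a named list of data.frames (names become file stems) or a
#'   single data.frame.
#' @param path output directory for a list, or the file path for a single
#'   data.frame.
#' @return Character vector of files written, invisibly.
#' @export
write_report_tables <- function(tables, path) {
  write_one <- function(df, file) {
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) formatC(x, format = "f", digits = 6))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    file
  }
  if (is.data.frame(tables)) return(invisible(write_one(tables, path)))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(names(tables), function(nm)
    write_one(tables[[nm]], file.path(path, paste0(nm, ".tsv"))), "")
  invisible(unname(files))
}
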