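# Small in-code fixtures shared across test files.

make_genes <- function(n, chrom_id = "c1", genome_id = "G1", L = 10000,
                       len = 300, cluster_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sort(sample.int(L - len, n))
  data.frame(
    gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
    genome_id = genome_id,
    chrom_id = chrom_id,
    start_bp = start,
    end_bp = start + len,
    strand = rep_len(c("+", "-"), n),
    cluster_id = if (is.null(cluster_id)) sprintf("CL%03d", seq_len(n))
                 else cluster_id,
    stringsAsFactors = FALSE
  )
}

make_chrom <- function(chrom_id = "c1", L = 10000, ori = 0, ter = NA) {
  data.frame(chrom_id = chrom_id, length_bp = L, ori_bp = ori,
             ter_bp = ter, stringsAsFactors = FALSE)
}

make_matrix <- function(occupancies, n_genomes) {
  m <- t(vapply(occupancies, function(o) {
    row <- integer(n_genomes)
    row[seq_len(o)] <- 1L
    row
  }, integer(n_genomes)))
  rownames(m) <- sprintf("CL%03d", seq_along(occupancies))
  colnames(m) <- sprintf("G%02d", seq_len(n_genomes))
  pangenome_matrix(m)
}

# Independent brute-force oracles ------------------------------------------

# shortest arc distance by explicit minimisation over both directions
brute_circular_distance <- function(pos, ori, L) {
  cw <- (pos - ori) %% L
  ccw <- (ori - pos) %% L
  min(cw, ccw)
}

# chi-square GOF statistic by direct summation
brute_chi2 <- function(obs, expected) sum((obs - expected)^2 / expected)

# exact two-sided rank-sum p-value by enumeration of all group assignments
brute_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# circular moving average by explicit index arithmetic
brute_circular_ma <- function(x, w) {
  n <- length(x)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo   # extra point forward for even w
  vapply(seq_len(n), function(i) {
    idx <- ((i - half_lo - 1):(i + half_hi - 1)) %% n + 1
    mean(x[idx])
  }, 0)
}
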