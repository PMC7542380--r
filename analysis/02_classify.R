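#!/usr/bin/env Rscript
# Stage 2: pangenome occupancy classification.
#
# Reads the cluster-by-genome matrix written by stage 1, classifies every
# cluster into core / softcore / shell / cloud by occupancy (softcore
# fraction 0.95, cloud max 2) and writes per-cluster assignments plus the
# category summary.

suppressMessages(library(replipan))

m <- read_pangenome_matrix("results/synthetic/pangenome_matrix.tsv")
thr <- category_thresholds(length(m$genome_ids))
cls <- classify_all(m, thr)

write_report_tables(list(cluster_categories = cls$assignments,
                         category_summary = cls$summary),
                    "results/classification")

s <- cls$summary
message("N = ", thr$n_genomes, " genomes; softcore threshold >= ",
        thr$softcore_min, " genomes")
for (i in seq_len(nrow(s)))
  message(sprintf("  %-8s %5d clusters (%.1f%%)", s$category[i],
                  s$count_exclusive[i], s$pct_exclusive[i]))
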