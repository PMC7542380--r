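#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# A 12-genome bipartite-genome pangenome with the default occupancy mixture
# (~1% core, 2% softcore, 23% shell, 74% cloud), positional bias b = 3 on
# the large chromosome only, and RNA-seq counts for one genome under fast
# (dosage exponent k = 1.5) and slow (k = 0) growth, three replicates each.
# Everything downstream reads the plain-text files written here.

suppressMessages(library(replipan))

out <- "results/synthetic"
cfg <- synthetic_config(seed = 20260922)
ds <- simulate_pangenome(cfg)
gid <- ds$genes$genome_id[1]
counts <- list(fast = simulate_counts(ds, cfg, "fast", genome_id = gid, n_reps = 3),
               slow = simulate_counts(ds, cfg, "slow", genome_id = gid, n_reps = 3))
files <- write_synthetic_dataset(ds, out, counts = counts)

message("genomes: ", cfg$n_genomes, "; clusters: ", cfg$n_clusters,
        "; genes: ", nrow(ds$genes))
message("expression genome: ", gid)
message("wrote ", length(files), " files under ", out)
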