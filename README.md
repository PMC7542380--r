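# replipan

Pangenome categories along the replichores of bipartite bacterial genomes.

Many *Vibrionaceae*-like bacteria carry two circular chromosomes and replicate
them in a highly ordered way. During fast growth, overlapping replication
rounds (multifork replication) raise the per-cell copy number of genes close
to the replication origin of the large chromosome (*ori1*), so a gene's
distance to *ori* is both a structural and a regulatory coordinate.
`replipan` asks how the four pangene categories — **core** (present in all N
genomes of a taxon), **softcore** (≥ ⌊0.95·N⌋ genomes), **shell**
(intermediate) and **cloud** (≤ 2 genomes) — are laid out along that
coordinate, and whether expression follows it. It is written for comparative
genomicists who have a pangenome presence/absence matrix, per-genome gene
coordinates, *ori* positions and (optionally) per-CDS RNA-seq counts.

## What it computes

* **Occupancy classification.** For a cluster-by-genome count matrix,
  occupancy is the number of genomes with ≥ 1 member (paralogs count once).
  With thresholds `softcore_min = ⌊f·N⌋` (default f = 0.95) and
  `cloud_max = 2`: core iff occupancy = N, softcore iff occupancy ≥
  softcore_min, cloud iff occupancy ≤ 2, shell otherwise. Both the nested
  view (core ⊆ softcore) and the exclusive partition are reported.
* **Circular geometry.** Each gene's midpoint m on a chromosome of length L
  gives d = min(|m−ori|, L−|m−ori|), the relative distance u = 2d/L ∈ [0,1],
  an ori-recentred signed coordinate in (−L/2, L/2], and a half: *upper*
  (ori-proximal, d < L/4) or *lower* (ter-proximal).
* **Positional bias.** Per (genome, chromosome, category), the upper/lower
  split is tested with a 1-df chi-square goodness-of-fit against a 50:50
  null (or a CDS-density-proportional null), Bonferroni-corrected over the
  scan.
* **Expression gradients.** RPKM = count / ((length/1000)·(total/10⁶));
  per-gene log2(RPKM / median RPKM) maps; a circular sliding-window trend
  (default 200 data points) along the recentred coordinate; per-category
  upper/lower quartile tables; unpaired Wilcoxon rank tests; and the OLS
  slope of log2(RPKM) on u, which estimates −k under the dosage model
  copy-number ∝ 2^(k·(1−u)).
* **Synthetic data.** A generator that plants all of the above — the
  U-shaped occupancy mixture, Beta-law positional bias on the large
  chromosome only, and Poisson counts with a 2^(k·(1−u)) dosage gradient —
  with a per-gene truth table, so calibration and recovery are quantifiable.

## Worked example

The `analysis/` directory is a numbered, re-runnable workflow over a
synthetic 12-genome dataset (run the scripts in order from the repository
root; outputs land under `results/`):

```sh
Rscript analysis/01_simulate.R        # genomes, matrix, counts
Rscript analysis/02_classify.R        # occupancy classification
Rscript analysis/03_positional_bias.R # halves, chi-square scan, Circos tracks
Rscript analysis/04_expression.R      # RPKM maps, quartiles, rank tests
Rscript analysis/05_recovery.R        # calibration & parameter recovery
```

Stage 2 prints the classification of the 6000 simulated clusters:

```
N = 12 genomes; softcore threshold >= 11 genomes
  core        90 clusters (1.5%)
  softcore    99 clusters (1.6%)
  shell     1408 clusters (23.5%)
  cloud     4403 clusters (73.4%)
```

Stage 3 shows the planted positional signature recovered by the
Bonferroni-adjusted chi-square scan — core/softcore upper-biased and
shell/cloud lower-biased on the large chromosome of every genome, nothing
on the small chromosome:

```
96 tests; 48 significant after Bonferroni
large chromosome, significant cells by category x direction:
           lower upper
  cloud       12     0
  core         0    12
  shell       12     0
  softcore    0     12
small chromosome: 0 significant cells
```

Stage 4 contrasts the growth conditions. At fast growth the dosage gradient
(planted k = 1.5) plus the category layout give a steep expression decay
with distance to ori and upper-half medians above lower-half medians; at
slow growth (k = 0) the core category is flat, while a residual global slope
remains because highly expressed core/softcore genes sit near ori:

```
fast growth: median RPKM 470.8; log2(RPKM) ~ rel_dist slope -3.21 (SE 0.09)
  core     upper median   4416.2  lower median   2577.0  p_adj 1.77e-05 *
  ...
slow growth: median RPKM 577.8; log2(RPKM) ~ rel_dist slope -1.81 (SE 0.09)
  core     upper median   2683.7  lower median   2505.2  p_adj 1
```

A `*` marks categories whose upper-half RPKM median differs significantly
from the lower half (Bonferroni-adjusted Wilcoxon, α = 0.05).

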