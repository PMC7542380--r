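---
title: "Pangene categories along the ori–ter axis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pangene categories along the ori-ter axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replipan)
```

This vignette is the package's account of its own methods: what is modelled,
which knobs matter, what the synthetic generator does and does not emulate,
and where the genuinely open design choices were settled.

## The analysis in one paragraph

A pangenome clustering of N genomes yields a cluster-by-genome count matrix.
Each cluster's *occupancy* (number of genomes with at least one member)
places it in one of four categories — core (all N), softcore
(≥ ⌊f·N⌋, default f = 0.95), cloud (≤ 2) and shell (the rest). Every gene
inherits its cluster's category and a position on its circular chromosome:
distance to the replication origin d, relative distance u = 2d/L, and a
half (*upper* = ori-proximal, *lower* = ter-proximal). The questions are
(i) whether categories are distributed non-randomly between halves
(chi-square per genome × chromosome × category, Bonferroni over the scan)
and (ii) whether expression follows the same axis (RPKM log2-ratio maps,
sliding-window trends, per-category quartiles and rank tests).

## Classification

Occupancy counts genomes, not gene copies: a paralogous cell value of 2
contributes 1. The softcore boundary is `floor(f * N)`; with N = 124 and
the default f = 0.95 the boundaries are core = 124, softcore ≥ 117, shell
3–116, cloud ≤ 2. The fraction f is a clustering-tool convention rather
than a biological constant, so it is a parameter, not a hard-coded value.

Two category views coexist. The *nested* view (softcore includes core) is
what clustering tools report; the *exclusive* view makes the four
categories a partition. All distribution and expression reporting defaults
to the exclusive view, because per-half counts and quartile tables are only
interpretable over disjoint groups. Per-genome counts published for real
pangenomes cannot disambiguate the two conventions, which is why both are
always computed and written.

## Geometry

* Gene position is the integer **midpoint** by default (`position_rule =
  "start"` is available). The midpoint is symmetric under strand and under
  wrapping of the linear coordinate, which is why it is the default; source
  annotations do not dictate a convention.
* A record with `end_bp <= start_bp` encodes a CDS spanning the linear
  origin of the circular sequence; the midpoint unwraps it modulo L.
* The terminus defaults to the antipode of ori, making the two halves equal
  arcs — this matches the 50:50 framing of the upper/lower split. An
  explicit `ter_bp` switches to a per-replichore-arc midpoint rule for
  unequal replichores, but it is off by default.
* Tie-break: a gene at exactly d = L/4 is *lower*. Ties are measure-zero
  but must be deterministic.
* Strand is carried through and ignored by every positional statistic.

## Bias testing

Each (genome, chromosome, category) cell is a 1-df goodness-of-fit
chi-square of (upper, lower) against expected counts. The default null is
**uniform** (E = n/2 per half): the halves are equal arcs by construction,
so under no positional preference a gene is equally likely in either. A
`cds_proportional` null is offered for the case where overall gene density
itself is biased; the choice is exposed rather than silently made because
either reading is defensible. Expected counts below 5 trigger a warning —
not an automatic switch of test, to keep the method transparent.

The Bonferroni family is *all tests executed in one scan* (e.g. 96 for 12
genomes × 2 chromosomes × 4 categories), the most conservative defensible
family; a per-(genome, chromosome) family is available. The alternative
framing of a 2×2 contingency of category-vs-rest would also give 1 df; the
goodness-of-fit reading is implemented because it matches testing each
category's own split.

## Expression

RPKM uses as denominator the **total reads assigned to CDS** of the genome
(both chromosomes), not the raw library size: alignment is out of scope,
counts are the input, and the two are monotone-equivalent within a sample.
Replicates are summed per gene before RPKM by default (per-replicate
processing is available).

The map statistic is log2(RPKM / median RPKM) with a single genome-wide
median per sample by default, so both chromosomes share one map centre; a
per-chromosome median is available. Zero-RPKM genes are imputed at ε = half
the smallest nonzero RPKM of the scope and flagged: imputed genes are
excluded from slope fits but retained in quartile tables, so categories
containing silent genes legitimately show Q1 = 0.

The trend is a centred moving average over **gene order** (not base pairs),
default window 200 data points, wrapping across ori because the chromosome
is circular (an even window puts its extra point forward in gene order —
the `stats::filter()` convention). Window 1 is the identity; the circular
mean preserves the input mean exactly.

The upper-vs-lower comparison uses the **unpaired** two-sample rank-sum
procedure (R's `wilcox.test()` with `paired` unset): the two groups are
different genes, so pairing is undefined. Exact enumeration applies for
small tie-free samples, the tie-corrected normal approximation otherwise;
p-values are Bonferroni-adjusted over the per-condition scan.

## The synthetic generator

The generator emulates exactly the structure the analysis assumes:

* **Occupancy mixture** ≈ (1.2%, 1.8%, 23%, 74%) for core/softcore/shell/
  cloud — the U-shaped distribution typical of large bacterial pangenomes.
  Within-category occupancies are uniform on their admissible ranges.
* **Positions.** On the large chromosome, u ~ Beta(1, 1+b) for
  core/softcore and Beta(1+b, 1) for shell/cloud; uniform on the small
  chromosome or when b = 0. The Beta family was chosen as the simplest
  one-parameter law with a closed-form mean (1/(2+b) toward ori), which
  makes planted effects analytically checkable. The default b = 3 puts
  roughly 94% of a biased category on its preferred half.
* **Counts.** Expected expression = baseline(category) · 2^(k·(1−u)) ·
  exp(ε), ε ~ N(0, σ²), Poisson-sampled with means scaled to the library
  size. The dosage law 2^(k·(1−u)) is the minimal monotone
  multifork-flavoured model: a gene at ori has 2^k times the copy number of
  a gene at ter. k is a generator parameter (fast ≈ 1.5, slow = 0), not an
  estimate of any organism's value. Poisson noise was preferred to negative
  binomial because the log-normal gene effect already supplies
  overdispersion while keeping RPKM behaviour analytically predictable.
* **Defaults as study conditions.** 12 genomes, chromosomes of 3.2 and
  1.8 Mb, 6000 clusters (desk-scale; a real family-level pangenome is an
  order of magnitude larger), gene lengths log-normal around ~900 bp,
  σ = 0.3, library size 5 × 10⁶. Genes that would span the linear origin
  are shifted flush to the sequence end so that emitted GFF3 is always
  valid; overlaps between genes are not prevented.

What the generator does **not** emulate: operon and rRNA-cluster structure,
local hotspots near ori or ter (regions dense in one category), GC skew,
leading/lagging strand effects, replication-timing dynamics, genuine
paralogy, or any mechanism by which non-core categories would stay biased
at slow growth (an optional `slow_residual_k` plants such a residual
gradient, clearly labelled as a stand-in). Passing recovery tests therefore
show the *pipeline* is correct and calibrated, not that real genomes obey
the Beta/dosage laws.

One emergent property is worth noting: because category baselines differ
(core genes are expressed above cloud genes) and categories are
positionally biased, the slow-growth (k = 0) expression map still shows a
negative slope along u. The per-category rank tests disentangle this:
within the core category, upper and lower medians are indistinguishable at
slow growth, while the global map slopes — the same dissociation the
per-category analysis is designed to expose.

## Problem sizes and numerical choices

The calibration and recovery experiments run at fixed, seeded sizes chosen
so the planted effects are estimated with comfortable precision: ≥ 2000
pooled null tests for type-I calibration (binomial SE ≈ 0.005 at α = 0.05);
50 replicates at ~2000 genes per category for the bias-pattern recovery
(per-cell chi-square power ≈ 1 at b = 3); ~3000 genes for the dosage-slope
fit (SE ≈ 0.08, so the planted k = 1.5 is a ~20-SE effect) and 30
slow-growth replicates for the core flatness rate. All randomness flows
from a single user-visible seed; identical seeds give byte-identical
datasets and reports.

Report writers emit floats at fixed 6-decimal precision in deterministic
column order, so repeated runs are diffable. The Circos writer recentres
coordinates at ori (position 0 = ori) and splits intervals that cross the
wrap point.

## Known limitations

* The chi-square scan assumes genes are independent draws; gene clustering
  (operons) inflates the effective significance of real data. Interpret
  adjusted p-values on real genomes with that caveat.
* The exact rank-sum path is only used for small tie-free samples; RPKM
  ties (e.g. many zero-count genes) route to the approximate path.
* `read_gff` requires chromosome lengths (sequence-region pragmas or a
  companion table); it deliberately refuses to guess lengths from the
  largest coordinate.
* GenBank input is supported only by converting to GFF3 first — one parser,
  one source of coordinate truth.
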