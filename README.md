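# atacwave

Analysis of replicated ATAC-seq time courses over an evolving cell
population — for epigenomics researchers who have called peaks and counted
fragments across a handful of timepoints and want to know *when* chromatin
compaction changed, *which* peaks follow coherent temporal programs, and
*what* those peaks are.

The package was built around a 28-day laboratory-evolution design assayed
at days 0, 3, 7, 10 and 28, with selection pressure applied between days 0
and 7: the hallmark result in such data is a **two-wave** pattern, with
differential compaction concentrated at the selection-onset (day 0→3) and
selection-release (day 7→10) transitions.

## What it computes

* **Differential accessibility between consecutive days.** Counts
  `K_ij ~ NB(s_j q_i(t), alpha_i)` are normalized with median-of-ratios
  size factors; per-peak dispersions are method-of-moments estimates
  shrunk toward a fitted trend `alpha(mu) = a0 + a1/mu`; the NB Wald test
  (log-link GLM, design `~ day`) yields `log2FC`, two-sided normal p, and
  Benjamini–Hochberg adjusted p, significant at `p_adj < 0.05`.
* **Dynamic-peak classification.** Each standardized profile `y(t)` is
  fitted with a zero-mean GP with RBF + white-noise covariance (dynamic)
  and with white noise alone (static);
  `LR = -2 (loglik_RBF - loglik_static) <= 0` is referred to chi-square
  with 1 df: strictly dynamic when `p < 0.05`, loosely dynamic when
  `LR < -0.25` (the clustering candidate pool).
* **Temporal clustering.** Loose-dynamic profiles are clustered with a
  mixture of hierarchical GPs (cluster-mean GP plus within-cluster
  GP + noise), EM with seeded restarts, truncation at `K_max` and
  BIC-guided component merging.
* **Composition tests.** Two-proportion Z statistic
  `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` comparing annotation-class
  frequencies (promoter-TSS/TES/exon/intergenic; mRNA/tRNA/other) in
  dynamic vs remaining peaks.
* **Gene-set enrichment.** Local hypergeometric over-representation and
  preranked running-sum GSEA (one entry per significant peak,
  label-permutation null, NES, FDR ≤ 0.1), plus flags for *reversible*
  sets — enriched with opposite signs at the onset and release
  transitions.
* **Synthetic studies.** A generator producing toy genomes, annotated
  peaks, gene sets and replicated NB count matrices with known dynamic
  and differential ground truth, so the whole pipeline is testable
  offline.

## Worked example

```r
library(atacwave)

cfg <- pipeline_config(sim = simulation_config(n_peaks = 800, seed = 2),
                       seed = 2)
res <- run_full(cfg, "run")
cat(readLines("run/report.txt"), sep = "\n")
```

which prints (abridged):

```
Peaks: 800; strictly dynamic: 41 (5.12%); loosely dynamic: 228 (28.5%)

Significant differential peaks per consecutive-day pair:
  day0_vs_day3: 6 up, 8 down (14 total)
  day3_vs_day7: 0 up, 0 down (0 total)
  day7_vs_day10: 4 up, 3 down (7 total)
  day10_vs_day28: 0 up, 0 down (0 total)

Cluster sizes:
  cluster 1: 34 peaks
  ...
Composition tests (dynamic vs rest):
  transcript/tRNA: Z = 1.82, p = 0.0685
  ...
```

Reading it: the generator injected effects only at the 0→3 and 7→10
transitions, and the differential stage finds significant peaks only
there — the two-wave signature. 5.1% of peaks pass the strict chi-square
dynamic test (the generator made 7.8% truly dynamic; weak-amplitude ones
are missed), while the loose `LR < -0.25` pool is much larger by design —
it is a candidate set for clustering, not a significance call.  Each
cluster groups peaks sharing one temporal shape; the composition Z tests
are null here because synthetic dynamics are independent of annotation.
Per-stage tables (`differential_*.tsv`, `dynamics.tsv`,
`cluster_assignments.tsv`, `composition.tsv`, `gsea_*.tsv`,
`reversible_sets.tsv`) and a manifest land in the output directory.

A thin CLI wraps the same functions:

```sh
inst/exec/atacwave simulate --out study --n-peaks 1000 --seed 3
inst/exec/atacwave run --out results --input study --seed 3
```

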