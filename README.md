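# scHybrid

Detection of tumor–macrophage **hybrid cells** (HCs) in droplet single-cell
RNA-seq and targeted in-situ spatial transcriptomics.

Hybrid cells co-express epithelial and monocyte/macrophage lineage
programs — the tissue-resident counterparts of circulating hybrid cells
implicated in metastasis. They are rare (~0.1–1% of cells) and easily
confused with droplet doublets, whose transcriptomes are also mixtures of
two cells. scHybrid packages the full identification framework for
analysts who want to find and characterize these cells in their own data:

* **Marker gate** — a cell is called hybrid iff raw counts satisfy
  *EPCAM* > 0 ∧ *KRT8* > 0 ∧ *CD14* > 0 ∧ *CD163* > 0 (markers and the
  detection threshold are configurable; a permissive two-marker
  *EPCAM*/*CD163* variant is included).
* **Doublet scoring** — a co-expression score (cxds: sum of
  mutual-exclusivity weights over co-detected gene pairs), a classifier
  score (bcds: gradient-boosted trees vs. artificial doublets,
  out-of-fold), their rank-normalized mean, and a mean + 2 SD (or fixed
  0.5) removal threshold: hybrid calls require score ≤ threshold.
* **Disambiguation** — an empirical placement null (where would real
  epithelial × myeloid doublets land among the clusters?), an exact
  two-sided binomial test of the observed myeloid skew of gated cells,
  and a Gaussian-mixture bimodality check (ΔBIC < −10) on their scores.
* **Differential expression** — two-sided Wilcoxon rank-sum per gene with
  `pct.1`, `pct.2`, `avg_log2FC = log2((mean(expm1(a))+1)/(mean(expm1(b))+1))`,
  Bonferroni over all genes; volcano annotation with −log10 p.
* **Preranked GSEA** — weighted Kolmogorov–Smirnov enrichment score with a
  gene-permutation null, signed-null NES, BH correction; GMT reader/writer.
* **Spatial mode** — MTX + centroid ingestion, the same gate without a
  doublet filter, mutually exclusive hybrid/epithelial/myeloid/other
  classes, viewer annotation export, neighborhood composition.
* **Synthetic benchmark generator** — negative-binomial programs with
  ground-truth hybrids (convex parental mixture, weight λ, plus an
  SPP1-like private signature) and droplet doublets (exact singlet sums),
  with tumor/normal tissue structure.

All heavy lifting behind standard steps uses established packages
(Matrix, SingleCellExperiment, scran/igraph for SNN graph clustering,
xgboost, mclust); the scientific layer — gates, scores, placement null,
exact tests, enrichment — is implemented and oracle-tested here.

## Worked example

```r
library(scHybrid)

cfg   <- simConfig(seed = 101)       # 5,000 cells, 2,000 genes, 1% hybrids,
sce   <- simulateDataset(cfg)        # 5% injected doublets, tumor/normal split
cx    <- scoreCxds(sce)
bc    <- scoreBcds(sce, seed = 101)
hy    <- combineHybridScore(cx, bc)
thr   <- deriveThreshold(hy, "mean_plus_2sd")
calls <- callHybrids(sce, gateSpec(applyDoubletFilter = TRUE,
                                   threshold = thr), hy)
calls
#> HybridCallSet: 43 / 5302 cells (0.811%) pass the gate
#> GateSpec: [EPCAM, KRT8] AND [CD14, CD163] >= 1
#>   doublet filter: score <= 0.9425615 (mean_plus_2sd)

truth <- simTruth(sce)
table(called = isHybrid(calls), truth = truth$true_label == "hybrid")
#>        truth
#> called  FALSE TRUE
#>   FALSE  5250    9
#>   TRUE      2   41

summarizeByGroup(calls, truth, "tissue")
#>    group n_cells n_hybrids    fraction
#> 1 normal    1587        11 0.006931317
#> 2  tumor    3715        32 0.008613728
```

Of the 50 planted hybrids, 41 survive gating plus the doublet filter
(recall 0.82) and only 2 of 43 calls are not true hybrids (precision
0.95); the doublet filter has removed every injected doublet that passed
the raw four-marker gate. The per-tissue fractions are consistent with
the 1% planted prevalence in both fractions. Downstream,
`doubletAssignmentNull()` / `placeInNullMap()` / `testMyeloidSkew()`
quantify the myeloid placement argument, `findMarkerGenes()` +
`prerankedGSEA()` characterize the hybrid transcriptome, and
`runPipeline()` chains everything into a seeded, hash-stamped run
directory.

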