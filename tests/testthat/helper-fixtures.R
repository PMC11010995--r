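# Shared fixtures, computed lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small dataset for fast unit tests (420 singlets + hybrids + doublets)
smallSimConfig <- function(seed = 42L, ...) {
  simConfig(nGenes = 300L,
            cellsPerType = c(epithelial = 150L, monocyte = 40L,
                             macrophage = 80L, other = 150L),
            hybridPrivateGenes = setNames(rep(2, 5),
                                          c("SPP1", "CD44", "HPG03",
                                            "HPG04", "HPG05")),
            hybridFraction = 0.02,
            seed = seed, ...)
}

smallDataset <- function() .cached("small", simulateDataset(smallSimConfig()))

# the default-scale benchmark: 5,000 singlet-scale cells, 2,000 genes,
# 1% hybrids, 5% injected doublets, doublet scores from all three methods
defaultBenchmark <- function() {
  .cached("benchmark", {
    cfg <- simConfig(seed = 101L)
    sce <- simulateDataset(cfg)
    cx <- scoreCxds(sce)
    bc <- scoreBcds(sce, seed = 101L)
    hy <- combineHybridScore(cx, bc)
    list(config = cfg, sce = sce, cxds = cx, bcds = bc, hybrid = hy,
         isDoublet = sce$true_label == "doublet",
         isHybrid = sce$true_label == "hybrid")
  })
}

# mid-size dataset (no doublets) with lambda fixed at 0.3 for the
# myeloid-skew analysis
skewDataset <- function() {
  .cached("skew", {
    cfg <- simConfig(
      nGenes = 1000L,
      cellsPerType = c(epithelial = 1000L, monocyte = 100L,
                       macrophage = 300L, other = 1100L),
      hybridFraction = 0.02, doubletRate = 0,
      mixingWeightRange = c(0.3, 0.3), seed = 57L)
    simulateCells(cfg)
  })
}
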