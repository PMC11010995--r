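test_that("gate calls match the per-cell brute-force oracle on random matrices", {
  genes <- sprintf("g%02d", 1:12)
  for (trial in 1:20) {
    set.seed(trial)
    nG <- sample(6:12, 1)
    nC <- sample(5:100, 1)
    m <- matrix(rpois(nG * nC, 0.7), nG, nC,
                dimnames = list(genes[1:nG], sprintf("c%03d", 1:nC)))
    epi <- sample(rownames(m), 2)
    mye <- sample(setdiff(rownames(m), epi), 2)
    mc <- sample(1:2, 1)
    useFilter <- trial %% 2 == 0
    scores <- runif(nC)
    thr <- deriveThreshold(method = "fixed", fixedValue = 0.5)
    gate <- gateSpec(epi, mye, mc, applyDoubletFilter = useFilter,
                     threshold = if (useFilter) thr else NULL)
    calls <- callHybrids(m, gate,
                         scores = if (useFilter) setNames(scores, colnames(m)))
    want <- oracleGateCalls(m, epi, mye, mc,
                            scores = if (useFilter) scores,
                            threshold = if (useFilter) 0.5)
    expect_identical(isHybrid(calls), want)
  }
})

test_that("the gate is a pure conjunction with boundary cells kept", {
  m <- matrix(1, 4, 3, dimnames = list(c("EPCAM", "KRT8", "CD14", "CD163"),
                                       c("all", "miss", "edge")))
  m["KRT8", "miss"] <- 0
  scores <- c(all = 0, miss = 0, edge = 0.5)   # boundary score == threshold
  thr <- deriveThreshold(method = "fixed", fixedValue = 0.5)
  calls <- callHybrids(m, gateSpec(applyDoubletFilter = TRUE,
                                   threshold = thr), scores)
  expect_setequal(hybridIds(calls), c("all", "edge"))
  expect_equal(nHybrids(calls), 2L)
  expect_equal(nTotal(calls), 3L)
  expect_error(callHybrids(m[1:3, ], gateSpec()), "CD163")
})

test_that("gate calls are invariant under normalization (raw-count semantics)", {
  sce <- smallDataset()
  counts <- SummarizedExperiment::assay(sce, "counts")
  callsRaw <- callHybrids(counts, gateSpec())
  # normalization never changes the gate input
  norm <- normalizeLog(counts)
  expect_identical(isHybrid(callHybrids(counts, gateSpec())),
                   isHybrid(callsRaw))
  expect_false(identical(norm, counts))
})

test_that("gates are monotone in markers and in the count threshold", {
  sce <- smallDataset()
  counts <- SummarizedExperiment::assay(sce, "counts")
  relaxed <- callHybridsRelaxed(counts, "EPCAM", "CD163")
  strict <- callHybrids(counts, gateSpec())
  wider <- callHybrids(counts, gateSpec(c("EPCAM", "KRT8", "KRT18"),
                                        c("CD14", "CD163")))
  expect_true(all(hybridIds(strict) %in% hybridIds(relaxed)))
  expect_true(all(hybridIds(wider) %in% hybridIds(strict)))
  mc2 <- callHybrids(counts, gateSpec(minCount = 2L))
  expect_true(all(hybridIds(mc2) %in% hybridIds(strict)))
  # empty matrix -> zero calls
  empty <- counts[, 0, drop = FALSE]
  expect_equal(nHybrids(callHybridsRelaxed(empty, "EPCAM", "CD163")), 0L)
})

test_that("group summaries give exact fractions including empty groups", {
  m <- matrix(1, 4, 6, dimnames = list(c("EPCAM", "KRT8", "CD14", "CD163"),
                                       sprintf("c%d", 1:6)))
  m["EPCAM", 4:6] <- 0
  cells <- data.frame(tissue = c("tumor", "tumor", "tumor",
                                 "normal", "normal", "normal"),
                      row.names = colnames(m))
  calls <- callHybrids(m, gateSpec())
  tab <- summarizeByGroup(calls, cells, "tissue")
  expect_equal(tab$fraction[tab$group == "tumor"], 1)
  expect_equal(tab$fraction[tab$group == "normal"], 0)
  expect_equal(tab$n_cells, c(3L, 3L))
  expect_error(summarizeByGroup(calls, cells, "stage"), "unknown group")
})

test_that("planted per-tissue hybrid fractions are recovered within binomial CI", {
  cfg <- simConfig(
    cellsPerType = c(epithelial = 4000L, monocyte = 300L,
                     macrophage = 800L, other = 4900L),
    hybridFraction = c(tumor = 0.002, normal = 0.0005),
    doubletRate = 0, seed = 77L)
  sce <- simulateCells(cfg)
  calls <- callHybrids(sce, gateSpec())
  tab <- summarizeByGroup(calls, simTruth(sce), "tissue")
  for (tis in c("tumor", "normal")) {
    planted <- if (tis == "tumor") 0.002 else 0.0005
    row <- tab[tab$group == tis, ]
    ci <- planted + c(-1, 1) * 1.96 * sqrt(planted * (1 - planted) /
                                           row$n_cells)
    expect_gte(row$fraction, max(ci[1], 0))
    expect_lte(row$fraction, ci[2] + 2 / row$n_cells)
  }
})

test_that("enrichment ratio reproduces the published arithmetic and identities", {
  expect_equal(enrichmentRatio(0.21, 0.05), 4.2)
  expect_equal(enrichmentRatio(0.3, 0.3), 1)
  expect_equal(enrichmentRatio(0.4, 0.1) * enrichmentRatio(0.1, 0.4), 1)
  expect_warning(r <- enrichmentRatio(0.2, 0), "zero")
  expect_identical(unname(c(r)), Inf)
  expect_true(attr(r, "infinite"))
})

test_that("cluster co-localization partitions hybrids across lineages", {
  calls <- new("HybridCallSet",
               isHybrid = c(a = TRUE, b = TRUE, c = TRUE, d = FALSE),
               gate = gateSpec())
  clusters <- c(a = 0L, b = 0L, c = 1L, d = 2L)
  ann <- data.frame(cluster = 0:2,
                    majority_type = c("macrophage", "epithelial", "other"))
  tab <- clusterColocalization(calls, clusters, ann)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$fraction[tab$lineage == "myeloid"], 2 / 3)
  expect_equal(tab$fraction[tab$lineage == "epithelial"], 1 / 3)
  # all hybrids in one myeloid cluster
  one <- clusterColocalization(
    new("HybridCallSet", isHybrid = c(a = TRUE, b = TRUE), gate = gateSpec()),
    c(a = 0L, b = 0L), data.frame(cluster = 0L, majority_type = "monocyte"))
  expect_equal(one$fraction[one$lineage == "myeloid"], 1)
  # unannotated cluster counted under other, with a warning
  expect_warning(
    miss <- clusterColocalization(calls, clusters,
                                  ann[ann$cluster != 2, ]), NA)
  clusters2 <- c(a = 0L, b = 5L, c = 1L, d = 2L)
  expect_warning(
    miss <- clusterColocalization(calls, clusters2, ann), "unannotated")
  expect_equal(miss$fraction[miss$lineage == "other"], 1 / 3)
})

test_that("macrophage-weighted hybrids co-localize with myeloid clusters", {
  sce <- skewDataset()
  pp <- preprocessCells(sce, preprocessConfig(nHVG = 500L))
  calls <- callHybrids(pp, gateSpec())
  truth <- simTruth(pp)
  ann <- majorityAnnotation(pp$cluster, annotateTruth(truth))
  tab <- clusterColocalization(calls, setNames(pp$cluster, colnames(pp)), ann)
  expect_gt(tab$fraction[tab$lineage == "myeloid"], 0.75)
})

test_that("upstream-style annotation assigns hybrids to their dominant parent", {
  sce <- smallDataset()
  truth <- simTruth(sce)
  ann <- annotateTruth(truth)
  hyb <- truth$true_label == "hybrid"
  expect_true(all(ann[hyb] %in% c("epithelial", "macrophage")))
  expect_identical(ann[hyb] == "epithelial",
                   unname(truth$lambda[hyb] >= 0.5))
  dbl <- truth$true_label == "doublet"
  expect_identical(ann[dbl],
                   as.character(truth[truth$parent1[dbl], "true_label"]))
  sing <- !hyb & !dbl
  expect_identical(ann[sing], as.character(truth$true_label[sing]))
})
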