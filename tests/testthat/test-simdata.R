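test_that("configuration invariants are enforced", {
  expect_error(simConfig(hybridFraction = 1.2), "proportions")
  expect_error(simConfig(mixingWeightRange = c(0, 0.5)), "strictly inside")
  expect_error(simConfig(markerGenes = list(
    epithelial = c("EPCAM", "CD14"),
    myeloid = c("CD14", "CD163"))), "disjoint")
  expect_error(simConfig(nGenes = 10), "cover")
})

test_that("programs give markers >= 10x enrichment in the owning lineage", {
  cfg <- smallSimConfig()
  prog <- makePrograms(cfg)
  for (lin in names(cfg@markerGenes)) {
    owns <- lineageOf(rownames(prog)) == lin
    for (g in cfg@markerGenes[[lin]]) {
      expect_gte(min(prog[owns, g]) / max(prog[!owns, g]), 10)
    }
  }
})

test_that("programs are deterministic given the seed", {
  cfg <- smallSimConfig(seed = 9L)
  expect_identical(makePrograms(cfg), makePrograms(cfg))
  expect_false(identical(makePrograms(cfg),
                         makePrograms(smallSimConfig(seed = 10L))))
})

test_that("non-marker program means follow the configured gamma law", {
  cfg <- simConfig(nGenes = 10000L,
                   cellsPerType = c(epithelial = 10L, macrophage = 10L),
                   seed = 3L)
  prog <- makePrograms(cfg)
  nonMarker <- setdiff(colnames(prog), unlist(cfg@markerGenes))
  x <- prog["epithelial", nonMarker]
  k <- cfg@gammaShape; th <- cfg@gammaScale
  se <- sqrt(k * th^2 / length(x))
  expect_lt(abs(mean(x) - k * th), 3 * se)
})

test_that("simulated singlet means match the NB expectation", {
  cfg <- simConfig(nGenes = 400L,
                   cellsPerType = c(epithelial = 2000L),
                   hybridFraction = 0, doubletRate = 0, seed = 11L)
  prog <- makePrograms(cfg)
  sce <- simulateCells(cfg, prog)
  counts <- SummarizedExperiment::assay(sce, "counts")
  p <- prog["epithelial", ] / sum(prog["epithelial", ])
  expLib <- exp(cfg@libsizeMeanlog + cfg@libsizeSdlog^2 / 2)
  mu <- p * expLib
  obs <- Matrix::rowMeans(counts)
  # per-gene NB + library variation: compare aggregate over genes binned by mu
  big <- mu > 1
  expect_lt(abs(sum(obs[big]) - sum(mu[big])) / sum(mu[big]), 0.05)
  # and per-gene within 5 SE for the strong markers
  for (g in unlist(cfg@markerGenes$epithelial)) {
    v <- mu[g] + cfg@nbDispersion * mu[g]^2 + (exp(cfg@libsizeSdlog^2) - 1) * mu[g]^2
    expect_lt(abs(obs[g] - mu[g]), 5 * sqrt(v / ncol(counts)))
  }
})

test_that("zero hybrid fraction and doublet rate yield pure singlets", {
  cfg <- simConfig(nGenes = 100L,
                   cellsPerType = c(epithelial = 30L, macrophage = 30L),
                   hybridFraction = 0, doubletRate = 0, seed = 2L)
  sce <- simulateDataset(cfg)
  expect_false(any(sce$true_label %in% c("hybrid", "doublet")))
  expect_equal(ncol(sce), 60L)
})

test_that("hybrids express all eight default markers and are truth-labelled", {
  sce <- smallDataset()
  counts <- SummarizedExperiment::assay(sce, "counts")
  cfg <- smallSimConfig()
  hyb <- sce$true_label == "hybrid"
  expect_gt(sum(hyb), 0)
  mk <- unlist(cfg@markerGenes)
  detection <- Matrix::rowMeans(counts[mk, hyb, drop = FALSE] > 0)
  expect_true(all(detection > 0.9))
  expect_true(all(!is.na(sce$lambda[hyb])))
  expect_true(all(is.na(sce$lambda[!hyb])))
})

test_that("expected epithelial-marker expression rises monotonically with lambda", {
  cfg <- smallSimConfig()
  prog <- makePrograms(cfg)
  lam <- seq(0.1, 0.9, by = 0.2)
  epiMean <- vapply(lam, function(l) {
    m <- l * prog["epithelial", ] + (1 - l) * prog["macrophage", ]
    sum(m[cfg@markerGenes$epithelial]) / sum(m)
  }, numeric(1))
  expect_true(all(diff(epiMean) > 0))
})

test_that("doublet count vectors equal their parents' sums exactly", {
  sce <- smallDataset()
  counts <- SummarizedExperiment::assay(sce, "counts")
  truth <- simTruth(sce)
  dbl <- which(truth$true_label == "doublet")
  expect_gt(length(dbl), 0)
  for (i in dbl) {
    expect_identical(counts[, i],
                     counts[, truth$parent1[i]] + counts[, truth$parent2[i]])
  }
  expect_true(all(!is.na(truth$parent1[dbl])))
  expect_true(all(is.na(truth$parent1[truth$true_label != "doublet"])))
})

test_that("doublet injection respects rate zero and the singlet minimum", {
  sce <- smallDataset()
  expect_identical(injectDoublets(sce, 0), sce)
  cfg <- simConfig(nGenes = 50L, cellsPerType = c(epithelial = 1L),
                   hybridFraction = 0, doubletRate = 0, seed = 1L)
  one <- simulateCells(cfg)
  expect_error(injectDoublets(one, 0.5), "2 singlet")
})

test_that("epi_myeloid parent mode restricts parent lineages", {
  cfg <- smallSimConfig(seed = 5L)
  sce <- simulateCells(cfg)
  out <- injectDoublets(sce, 0.1, seed = 5L, parentMode = "epi_myeloid")
  truth <- simTruth(out)
  dbl <- truth$true_label == "doublet"
  p1Lab <- truth[truth$parent1[dbl], "true_label"]
  p2Lab <- truth[truth$parent2[dbl], "true_label"]
  expect_true(all(p1Lab == "epithelial"))
  expect_true(all(lineageOf(p2Lab) == "myeloid"))
})

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- smallSimConfig(seed = 8L)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(as.data.frame(simTruth(a)), as.data.frame(simTruth(b)))
})

test_that("each marker separates its owning lineage from the others", {
  cfg <- simConfig(nGenes = 500L,
                   cellsPerType = c(epithelial = 500L, monocyte = 500L,
                                    macrophage = 500L, other = 500L),
                   hybridFraction = 0, doubletRate = 0, seed = 21L)
  sce <- simulateCells(cfg)
  counts <- SummarizedExperiment::assay(sce, "counts")
  lin <- lineageOf(sce$true_label)
  for (l in c("epithelial", "myeloid")) {
    for (g in cfg@markerGenes[[l]]) {
      p <- wilcox.test(as.numeric(counts[g, lin == l]),
                       as.numeric(counts[g, lin != l]))$p.value
      expect_lt(p, 1e-6)
    }
  }
})

test_that("tumor and normal fractions carry the configured myeloid imbalance", {
  sce <- defaultBenchmark()$sce
  truth <- simTruth(sce)
  singlet <- !truth$true_label %in% c("hybrid", "doublet")
  lin <- lineageOf(truth$true_label)
  fT <- mean(lin[singlet & truth$tissue == "tumor"] == "myeloid")
  fN <- mean(lin[singlet & truth$tissue == "normal"] == "myeloid")
  expect_gt(fT, 3 * fN)      # strong tumor myeloid infiltration
  expect_equal(fT, 0.148, tolerance = 0.1)
  expect_equal(fN, 0.024, tolerance = 0.25)
})

test_that("MTX export round-trips counts and truth", {
  sce <- smallDataset()
  dir <- withr::local_tempdir()
  writeCountsMTX(sce, dir)
  back <- readCountsMTX(dir)
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(SummarizedExperiment::assay(sce, "counts")))
  expect_identical(back$true_label, sce$true_label)
  expect_equal(back$lambda, sce$lambda)
})

test_that("spatial simulation restricts to the panel and stays in bounds", {
  cfg <- smallSimConfig(seed = 13L)
  panel <- c("EPCAM", "KRT8", "CD14", "CD163", "SPP1", "g0001", "g0002")
  field <- c(800, 600)
  sp <- simulateSpatial(cfg, panel, field = field, mode = "niche")
  expect_setequal(attr(sp$table, "genes"), panel)
  expect_true(all(sp$table$x_centroid >= 0 & sp$table$x_centroid <= field[1]))
  expect_true(all(sp$table$y_centroid >= 0 & sp$table$y_centroid <= field[2]))
  expect_equal(nrow(sp$table), nrow(sp$truth))
  expect_error(simulateSpatial(cfg, character(0)), "panel")
  expect_error(simulateSpatial(cfg, "NOT_A_GENE"), "not simulated")
})

test_that("full-panel spatial counts equal the scRNA simulation", {
  cfg <- simConfig(nGenes = 100L,
                   cellsPerType = c(epithelial = 40L, macrophage = 40L),
                   hybridFraction = 0, doubletRate = 0, seed = 4L)
  sce <- simulateCells(cfg)
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  sp <- simulateSpatial(cfg, rownames(sce), mode = "uniform")
  genes <- attr(sp$table, "genes")
  expect_equal(t(as.matrix(sp$table[, genes])), counts,
               ignore_attr = TRUE)
})

test_that("niche mode places same-type cells closer than different-type cells", {
  cfg <- smallSimConfig(seed = 17L)
  sp <- simulateSpatial(cfg, c("EPCAM", "CD163"), mode = "niche",
                        field = c(2000, 2000), nicheSd = 50)
  tab <- sp$table
  lab <- sp$truth$true_label
  xy <- cbind(tab$x_centroid, tab$y_centroid)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  same <- outer(lab, lab, "==")
  nnSame <- mean(apply(ifelse(same, d, Inf), 1, min))
  nnDiff <- mean(apply(ifelse(!same, d, Inf), 1, min))
  expect_lt(nnSame, nnDiff)
})
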