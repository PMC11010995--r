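test_that("Wilcoxon p-values match exhaustive 5-vs-5 split enumeration", {
  set.seed(6)
  for (trial in 1:5) {
    vals <- sample(seq(1, 40), 10)          # distinct -> no ties
    m <- matrix(log1p(vals), nrow = 1,
                dimnames = list("g1", sprintf("c%d", 1:10)))
    de <- findMarkerGenes(rbind(m, g2 = rep(c(0, 6), 5)),
                          sprintf("c%d", 1:5), sprintf("c%d", 6:10),
                          minPct = 0, logfcThreshold = 0)
    want <- oracleWilcoxP(m[1, 1:5], m[1, 6:10])
    expect_equal(de$p_val[de$gene == "g1"], want, tolerance = 1e-12)
  }
})

test_that("DE metrics follow the toolkit conventions", {
  norm <- rbind(
    up   = c(2, 2.5, 3, 2.2, 0.1, 0.2, 0.0, 0.1),
    flat = c(1, 1.1, 0.9, 1, 1, 1.05, 0.95, 1),
    off  = c(0, 0, 0, 0, 0, 0, 0, 0))
  colnames(norm) <- sprintf("c%d", 1:8)
  a <- sprintf("c%d", 1:4); b <- sprintf("c%d", 5:8)
  de <- findMarkerGenes(norm, a, b, minPct = 0, logfcThreshold = 0)
  up <- de[de$gene == "up", ]
  expect_equal(up$`pct.1`, 1)
  expect_equal(up$`pct.2`, 0.75)
  expect_equal(up$avg_log2FC,
               log2((mean(expm1(norm["up", a])) + 1) /
                    (mean(expm1(norm["up", b])) + 1)))
  # Bonferroni over ALL matrix genes (3), capped at 1
  expect_equal(de$p_val_adj, pmin(1, de$p_val * 3))
  expect_true(all(de$p_val_adj >= de$p_val))
  # sorted by p
  expect_true(!is.unsorted(de$p_val))
})

test_that("label swapping negates the fold change and swaps detection fractions", {
  sce <- smallDataset()
  norm <- normalizeLog(sce)
  truth <- simTruth(sce)
  a <- colnames(sce)[truth$true_label == "epithelial"][1:50]
  b <- colnames(sce)[truth$true_label == "macrophage"][1:50]
  d1 <- findMarkerGenes(norm, a, b, minPct = 0, logfcThreshold = 0)
  d2 <- findMarkerGenes(norm, b, a, minPct = 0, logfcThreshold = 0)
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d1$avg_log2FC, -d2$avg_log2FC)
  expect_equal(d1$`pct.1`, d2$`pct.2`)
  expect_equal(d1$p_val, d2$p_val, tolerance = 1e-12)
})

test_that("pre-filtering and input validation behave as specified", {
  norm <- matrix(abs(rnorm(40)), 4, 10,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:10)))
  expect_error(findMarkerGenes(norm, 1:5, 4:8), "disjoint")
  expect_error(findMarkerGenes(norm, 1:2, 3:10), "3 cells")
  norm["g1", ] <- c(rep(0.01, 5), rep(0, 5))  # low lfc, low pct
  de <- findMarkerGenes(norm, 1:5, 6:10, minPct = 0.9, logfcThreshold = 3)
  expect_false("g1" %in% de$gene)
})

test_that("the null type-I error rate is controlled at 5%", {
  cfg <- simConfig(nGenes = 2000L, cellsPerType = c(other = 200L),
                   hybridFraction = 0, doubletRate = 0, seed = 14L)
  sce <- simulateCells(cfg)
  norm <- normalizeLog(sce)
  set.seed(14)
  idx <- sample(ncol(norm))
  a <- idx[1:100]; b <- idx[101:200]
  de <- findMarkerGenes(norm, a, b, minPct = 0, logfcThreshold = 0)
  detected <- de[de$`pct.1` + de$`pct.2` > 0, ]
  rate <- mean(detected$p_val < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nrow(detected))
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("one-vs-rest markers recover the planted programs", {
  sce <- smallDataset()
  norm <- normalizeLog(sce)
  truth <- simTruth(sce)
  keep <- truth$true_label %in% c("epithelial", "macrophage", "other")
  all <- findAllMarkerGenes(norm[, keep], truth$true_label[keep])
  cfg <- smallSimConfig()
  epiTab <- all[all$cluster == "epithelial" & all$avg_log2FC > 0, ]
  topEpi <- head(epiTab$gene[order(-epiTab$avg_log2FC)], 10)
  expect_true(all(cfg@markerGenes$epithelial %in% topEpi))
  macTab <- all[all$cluster == "macrophage" & all$avg_log2FC > 0, ]
  topMac <- head(macTab$gene[order(-macTab$avg_log2FC)], 10)
  expect_true(all(cfg@markerGenes$myeloid %in% topMac))
  expect_lte(nrow(all), 3 * nrow(norm))
  # two clusters: tables are mirror images
  two <- findAllMarkerGenes(norm[, truth$true_label %in%
                                   c("epithelial", "macrophage")],
                            truth$true_label[truth$true_label %in%
                                               c("epithelial", "macrophage")])
  t1 <- two[two$cluster == "epithelial", ]
  t2 <- two[two$cluster == "macrophage", ]
  t2 <- t2[match(t1$gene, t2$gene), ]
  expect_equal(t1$avg_log2FC, -t2$avg_log2FC)
  expect_warning(expect_warning(
    findAllMarkerGenes(norm[, 1:10], c(rep("a", 9), "b")), "skipped"),
    "skipped")
})

test_that("volcano annotation adds capped -log10 p and significance flags", {
  de <- data.frame(gene = c("a", "b", "c"),
                   p_val = c(0.01, 0, 0.5),
                   avg_log2FC = c(1, 2, 0),
                   p_val_adj = c(0.04, 0, 1))
  v <- volcanoTable(de)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$neg_log10_p[3], -log10(0.5))
  expect_true(is.finite(v$neg_log10_p[2]) && v$p_zero[2])
  expect_identical(v$significant, c(TRUE, TRUE, FALSE))
  # monotone: smaller p, larger -log10 p
  expect_true(all(diff(v$neg_log10_p[order(v$p_val)]) <= 0))
})

test_that("DE ranking extraction is deterministic and validated", {
  de <- data.frame(gene = c("b", "a", "c"), avg_log2FC = c(1, 2, 1))
  r <- rankFromDE(de)
  expect_identical(names(r), c("a", "b", "c"))   # tie b/c broken by name
  expect_equal(unname(r), c(2, 1, 1))
  expect_error(rankFromDE(data.frame(gene = c("a", "a"),
                                     avg_log2FC = c(1, 2))), "duplicate")
  one <- rankFromDE(data.frame(gene = "x", avg_log2FC = 0.5))
  expect_identical(names(one), "x")
})

test_that("DE tables round-trip through TSV with exact column names", {
  de <- data.frame(gene = c("a", "b"), p_val = c(0.1, 0.2),
                   avg_log2FC = c(1, -1), `pct.1` = c(0.5, 0.1),
                   `pct.2` = c(0.1, 0.6), p_val_adj = c(0.2, 0.4),
                   check.names = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDETable(de, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("gene", "p_val", "avg_log2FC", "pct.1", "pct.2",
                          "p_val_adj"))
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back, de)
})
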