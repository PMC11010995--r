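# Wilcoxon marker differential expression with detection-fraction and
# fold-change metrics (pct.1 / pct.2 / avg_log2FC / Bonferroni p_val_adj).

.wilcoxP <- function(a, b) {
  # a gene with no variation at all carries no evidence
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
}

#' Differential expression between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test on log-normalized values
#' (exact below 50 cells per group without ties, otherwise the normal
#' approximation with tie and continuity correction), the detection
#' fractions in each group (`pct.1`, `pct.2`), and
#' `avg_log2FC = log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))` — the
#' back-transformed pseudocounted mean ratio. Genes are pre-filtered to
#' `max(pct.1, pct.2) >= minPct` and `|avg_log2FC| >= logfcThreshold`;
#' adjusted p-values are Bonferroni over ALL genes in the matrix.
#'
#' @param normalized log-normalized genes-by-cells matrix.
#' @param groupA,groupB disjoint cell id (or index) vectors, each with at
#'   least 3 cells.
#' @param minPct minimum detection fraction in the better-detected group.
#' @param logfcThreshold minimum absolute `avg_log2FC`.
#' @return data.frame sorted by `p_val` with columns `gene`, `p_val`,
#'   `avg_log2FC`, `pct.1`, `pct.2`, `p_val_adj`.
#' @export
findMarkerGenes <- function(normalized, groupA, groupB,
                            minPct = 0.1, logfcThreshold = 0.25) {
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs at least 3 cells")
  A <- normalized[, groupA, drop = FALSE]
  B <- normalized[, groupB, drop = FALSE]
  pct1 <- round(Matrix::rowMeans(A > 0), 3)
  pct2 <- round(Matrix::rowMeans(B > 0), 3)
  meanA <- Matrix::rowMeans(expm1(A))
  meanB <- Matrix::rowMeans(expm1(B))
  lfc <- log2((meanA + 1) / (meanB + 1))
  keep <- which(pmax(pct1, pct2) >= minPct & abs(lfc) >= logfcThreshold)
  Ad <- as.matrix(A[keep, , drop = FALSE])
  Bd <- as.matrix(B[keep, , drop = FALSE])
  p <- vapply(seq_along(keep),
              function(i) .wilcoxP(Ad[i, ], Bd[i, ]), numeric(1))
  nGenesTotal <- nrow(normalized)
  out <- data.frame(
    gene = rownames(normalized)[keep],
    p_val = p,
    avg_log2FC = lfc[keep],
    `pct.1` = pct1[keep],
    `pct.2` = pct2[keep],
    p_val_adj = p.adjust(p, method = "bonferroni", n = nGenesTotal),
    row.names = NULL, check.names = FALSE)
  out[order(out$p_val, out$gene), , drop = FALSE]
}

#' One-vs-rest differential expression per cluster
#'
#' Applies [findMarkerGenes()] for every cluster against its complement;
#' clusters too small to test (fewer than 3 cells) are skipped with a
#' warning.
#'
#' @param normalized log-normalized genes-by-cells matrix.
#' @param clusters per-cell cluster labels (aligned to columns).
#' @param ... passed to [findMarkerGenes()].
#' @return data.frame as in [findMarkerGenes()] with a leading `cluster`
#'   column.
#' @export
findAllMarkerGenes <- function(normalized, clusters, ...) {
  levs <- sort(unique(clusters))
  if (length(levs) < 2L) stop("need at least 2 clusters")
  idx <- seq_len(ncol(normalized))
  out <- lapply(levs, function(cl) {
    inCl <- idx[clusters == cl]
    if (length(inCl) < 3L || length(idx) - length(inCl) < 3L) {
      warning("cluster ", cl, " leaves fewer than 3 cells on one side; ",
              "skipped")
      return(NULL)
    }
    de <- findMarkerGenes(normalized, inCl, idx[clusters != cl], ...)
    if (nrow(de)) cbind(cluster = cl, de) else NULL
  })
  do.call(rbind, out)
}

#' Annotate a DE table for volcano plotting
#'
#' Adds `neg_log10_p = -log10(p_val)` (zero p-values are capped at the
#' largest representable magnitude and flagged in `p_zero`) and a
#' `significant` flag for `p_val_adj < alpha`.
#'
#' @param de a [findMarkerGenes()] table.
#' @param alpha adjusted-p significance cutoff.
#' @return the table with `neg_log10_p`, `p_zero` and `significant`
#'   columns.
#' @export
volcanoTable <- function(de, alpha = 0.05) {
  cap <- -log10(.Machine$double.xmin)
  zero <- de$p_val == 0
  nl <- -log10(de$p_val)
  nl[zero] <- cap
  de$neg_log10_p <- nl
  de$p_zero <- zero
  de$significant <- de$p_val_adj < alpha
  de
}

#' Ranking metric for preranked enrichment
#'
#' Extracts the `avg_log2FC` metric per gene, ordered decreasing with
#' deterministic tie-breaking by gene name.
#'
#' @param de a DE table with unique `gene` entries.
#' @return named numeric vector (gene -> metric), sorted decreasing.
#' @export
rankFromDE <- function(de) {
  if (anyDuplicated(de$gene)) stop("duplicate genes in DE table")
  stats <- setNames(de$avg_log2FC, de$gene)
  stats[order(-stats, names(stats))]
}

#' Write a DE table as TSV
#'
#' Column names (`gene`, `p_val`, `avg_log2FC`, `pct.1`, `pct.2`,
#' `p_val_adj`, and `neg_log10_p` when present) are preserved exactly for
#' downstream ranking tools.
#'
#' @param de a DE table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDETable <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
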