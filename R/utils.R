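#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score against binary labels; used to
#' benchmark doublet scores against simulation ground truth.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels logical (or 0/1) ground-truth labels.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# rank-normalize to [0, 1]; ties share the average rank
.rankUnit <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0.5, n))
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

.assayCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else x
}

#' Write a count matrix as an MTX trio with cell metadata
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and, when `x` is a
#' [SingleCellExperiment::SingleCellExperiment] with column metadata, a
#' `cells.csv` with the per-cell annotations (sample, tissue, ground-truth
#' label, mixing weight).
#'
#' @param x a `SingleCellExperiment` or a genes-by-cells (sparse) matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- .assayCounts(x)
  Matrix::writeMM(as(as(counts, "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (is(x, "SingleCellExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- cbind(cell_id = colnames(x), cd)
    write.csv(cd, file.path(dir, "cells.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read an MTX trio (plus optional cell metadata) back into a
#' SingleCellExperiment
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `cells.csv`.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @export
readCountsMTX <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  cellsFile <- file.path(dir, "cells.csv")
  if (file.exists(cellsFile)) {
    cd <- read.csv(cellsFile, stringsAsFactors = FALSE)
    stopifnot(identical(cd$cell_id, colnames(m)))
    rownames(cd) <- cd$cell_id
    SummarizedExperiment::colData(sce) <-
      S4Vectors::DataFrame(cd[, setdiff(names(cd), "cell_id"), drop = FALSE])
  }
  sce
}

#' Ground-truth simulation labels of a simulated dataset
#'
#' @param sce a `SingleCellExperiment` produced by [simulateCells()] /
#'   [simulateDataset()].
#' @return A `DataFrame` with columns `sample_id`, `tissue`, `true_label`,
#'   `lambda`, `parent1`, `parent2`.
#' @export
simTruth <- function(sce) {
  SummarizedExperiment::colData(sce)
}
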