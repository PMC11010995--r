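# Normalization, HVG selection, PCA and graph clustering.

#' Library-size log-normalization
#'
#' `log(1 + count / libsize * targetSum)` per entry; the sparsity pattern
#' and cell order are preserved.
#'
#' @param counts genes-by-cells matrix (dense or `dgCMatrix`) or a
#'   `SingleCellExperiment` (its `counts` assay is used).
#' @param targetSum counts-per-cell scaling constant.
#' @return normalized matrix of the same class/shape as the input counts.
#' @export
normalizeLog <- function(counts, targetSum = 1e4) {
  counts <- .assayCounts(counts)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("cell(s) with zero library size: ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (is(counts, "CsparseMatrix")) {
    out <- as(counts, "dMatrix")
    perCol <- rep.int(lib, diff(out@p))
    out@x <- log1p(out@x / perCol * targetSum)
    out
  } else {
    log1p(sweep(as.matrix(counts), 2, lib, "/") * targetSum)
  }
}

.rowVarsSparse <- function(x) {
  mu <- Matrix::rowMeans(x)
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  ex2 <- Matrix::rowMeans(x^2)
  (ex2 - mu^2) * n / (n - 1)
}

#' Highly variable gene selection
#'
#' Genes are scored by dispersion (variance / mean of the normalized
#' values), robustly standardized (median/MAD) within mean-expression bins
#' so that selection is not dominated by expression level, and the top
#' `nHVG` are returned.
#' `force` genes (e.g. the gate markers) are always retained when present.
#'
#' @param normalized normalized genes-by-cells matrix.
#' @param nHVG number of genes to select.
#' @param force genes appended to the selection regardless of rank.
#' @param nBins number of mean-expression bins for standardization.
#' @return character vector of selected gene ids.
#' @export
selectHVG <- function(normalized, nHVG, force = character(), nBins = 20L) {
  stopifnot(nHVG <= nrow(normalized))
  mu <- Matrix::rowMeans(normalized)
  v <- .rowVarsSparse(normalized)
  disp <- ifelse(mu > 0, v / mu, 0)
  # quantile bins on mean expression, kept wide enough (>= 50 genes) that a
  # handful of genuinely variable genes cannot monopolize a bin; robust
  # median/MAD standardization within each bin
  nBins <- max(1L, min(nBins, floor(nrow(normalized) / 50)))
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = nBins + 1L)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  z <- disp
  for (b in unique(bin)) {
    idx <- which(bin == b)
    s <- stats::mad(disp[idx])
    if (is.na(s) || s == 0) s <- sd(disp[idx])
    if (is.na(s) || s == 0) s <- 1
    z[idx] <- (disp[idx] - stats::median(disp[idx])) / s
  }
  genes <- rownames(normalized)
  ord <- order(-z, genes)
  sel <- genes[ord][seq_len(nHVG)]
  union(sel, intersect(force, genes))
}

#' PCA embedding
#'
#' Centered (unscaled) PCA of cells over genes. Components are ordered by
#' decreasing explained variance and sign-fixed so that each component's
#' largest-magnitude gene loading is positive, making embeddings
#' reproducible across platforms.
#'
#' @param normalized normalized genes-by-cells matrix.
#' @param nPCs number of components to return; if the matrix rank is lower,
#'   the available components are returned with a warning.
#' @return cells-by-components score matrix with attributes `sdev`,
#'   `rotation` (gene loadings) and `center` (gene means), needed to
#'   project new cells into the same space.
#' @export
embedPCA <- function(normalized, nPCs) {
  X <- t(as.matrix(normalized))
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  tol <- pr$sdev[1] * 1e-8
  rank <- sum(pr$sdev > tol)
  if (rank < nPCs) {
    warning("matrix rank ", rank, " is below requested ", nPCs,
            " components; returning ", rank)
    nPCs <- rank
  }
  keep <- seq_len(nPCs)
  rot <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(scores, sdev = pr$sdev[keep], rotation = rot,
            center = pr$center)
}

#' Graph-based clustering
#'
#' Builds a shared nearest-neighbor graph on the embedding (Jaccard edge
#' weights) and partitions it by modularity community detection
#' (Leiden refinement), reproducing the KNN-graph / resolution-0.8
#' clustering contract.
#'
#' @param embedding cells-by-components matrix from [embedPCA()].
#' @param knnK number of nearest neighbors.
#' @param resolution modularity resolution (> 0).
#' @param seed seed making the partition deterministic.
#' @return integer cluster labels (0-based, contiguous, ordered by
#'   decreasing cluster size), named by cell.
#' @export
clusterGraph <- function(embedding, knnK = 20L, resolution = 0.8, seed = 0L) {
  if (nrow(embedding) < knnK + 1L)
    stop("need at least knnK + 1 cells")
  g <- scran::buildSNNGraph(t(embedding), k = knnK, d = NA, type = "jaccard")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10L)
  memb <- as.integer(igraph::membership(cl))
  # relabel 0-based by decreasing size (ties: first-seen order)
  tab <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(tab) - 1L, names(tab))
  out <- unname(relabel[as.character(memb)])
  names(out) <- rownames(embedding)
  out
}

#' Majority-vote cluster annotation
#'
#' Maps each cluster to the plurality cell type of its members (ties broken
#' by lexicographic type name) together with the purity fraction.
#'
#' @param clusters integer cluster labels named by cell.
#' @param cellTypes type label per cell (same order/names as `clusters`).
#' @return data.frame with columns `cluster`, `majority_type`, `purity`,
#'   `n_cells`.
#' @export
majorityAnnotation <- function(clusters, cellTypes) {
  stopifnot(length(clusters) == length(cellTypes))
  if (anyNA(cellTypes)) stop("every cell must have a type label")
  levs <- sort(unique(clusters))
  out <- lapply(levs, function(cl) {
    tab <- table(cellTypes[clusters == cl])   # names sorted -> lexicographic ties
    data.frame(cluster = cl,
               majority_type = names(tab)[which.max(tab)],
               purity = max(tab) / sum(tab),
               n_cells = sum(tab))
  })
  do.call(rbind, out)
}

#' One-call preprocessing of a SingleCellExperiment
#'
#' Adds `logcounts`, selects HVGs (gate markers force-retained), computes
#' the PCA embedding on the HVG submatrix, and clusters cells, storing
#' results in the object (`reducedDim "PCA"`, `colData$cluster`, HVG ids in
#' `metadata(sce)$hvg`).
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param config a [preprocessConfig()].
#' @return the annotated `SingleCellExperiment`.
#' @export
preprocessCells <- function(sce, config = preprocessConfig()) {
  stopifnot(is(config, "PreprocessConfig"))
  norm <- normalizeLog(sce, config@targetSum)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  hvg <- selectHVG(norm, min(config@nHVG, nrow(sce)),
                   force = config@forceGenes)
  emb <- embedPCA(norm[hvg, , drop = FALSE], config@nPCs)
  cl <- clusterGraph(emb, config@knnK, config@resolution, config@seed)
  SingleCellExperiment::reducedDim(sce, "PCA") <- emb
  sce$cluster <- unname(cl)
  S4Vectors::metadata(sce)$hvg <- hvg
  sce
}
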