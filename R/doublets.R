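# Doublet scoring: co-expression (cxds), classifier (bcds), rank-combined.

#' Co-expression doublet score (cxds)
#'
#' Counts are binarized to detection calls. For every gene pair the score
#' weight is the standardized deficit of observed co-detection below the
#' independence expectation `n * p_i * p_j` — the larger the weight, the
#' more mutually exclusive the pair in singlets. A cell's score is the sum,
#' over the `nTopPairs` most exclusive (positive-weight) pairs, of the pair
#' weight times an indicator that the cell detects both genes. Cells
#' co-detecting many normally exclusive pairs (doublets, and genuine
#' hybrids) score high. The score depends only on the detection pattern,
#' never on count magnitude.
#'
#' @param counts genes-by-cells count matrix or `SingleCellExperiment`.
#' @param nTopPairs number of top mutually-exclusive pairs summed
#'   (clamped, with a warning, to the number of positive-weight pairs).
#' @return numeric per-cell score (named), `>= 0`.
#' @export
scoreCxds <- function(counts, nTopPairs = 500L) {
  counts <- .assayCounts(counts)
  B <- as(Matrix::Matrix(counts > 0, sparse = TRUE), "CsparseMatrix") * 1
  n <- ncol(B)
  det <- Matrix::rowSums(B)
  if (sum(det > 0) < 2L) stop("need at least 2 genes detected in >= 1 cell")
  p <- det / n
  O <- as.matrix(Matrix::tcrossprod(B))      # observed co-detection counts
  E <- n * outer(p, p)
  W <- (E - O) / sqrt(E * (1 - outer(p, p)) + 1e-8)
  ut <- upper.tri(W)
  wij <- W[ut]
  idx <- which(ut, arr.ind = TRUE)
  pos <- which(wij > 0)
  if (length(pos) == 0L) {
    warning("no mutually exclusive gene pairs; all scores are zero")
    return(setNames(numeric(n), colnames(B)))
  }
  if (nTopPairs > length(pos)) {
    warning("nTopPairs clamped to ", length(pos), " positive-weight pairs")
    nTopPairs <- length(pos)
  }
  # deterministic ordering: weight desc, then row/col index
  ord <- pos[order(-wij[pos], idx[pos, 1], idx[pos, 2])][seq_len(nTopPairs)]
  gi <- idx[ord, 1]; gj <- idx[ord, 2]
  used <- sort(unique(c(gi, gj)))
  Bd <- as.matrix(B[used, , drop = FALSE])
  ri <- match(gi, used); rj <- match(gj, used)
  score <- numeric(n)
  for (k in seq_along(ord)) {
    score <- score + wij[ord[k]] * (Bd[ri[k], ] * Bd[rj[k], ])
  }
  setNames(as.numeric(score), colnames(B))
}

#' Classifier doublet score (bcds)
#'
#' Generates artificial doublets by summing random cell pairs, then trains
#' a gradient-boosted tree classifier (observed vs. artificial) on
#' log-normalized highly-variable-gene features. Out-of-fold
#' cross-prediction is used so every observed cell is scored by a model
#' that never saw it.
#'
#' @param counts genes-by-cells count matrix or `SingleCellExperiment`
#'   (>= 100 cells).
#' @param nArtificial number of artificial doublets (default: one per
#'   observed cell).
#' @param seed integer seed (sampling and boosting are deterministic given
#'   it).
#' @param nHVG number of feature genes.
#' @param nFolds cross-prediction folds.
#' @param nRounds,maxDepth,eta boosting parameters.
#' @return numeric per-cell doublet probability in \[0, 1\] (named).
#' @export
scoreBcds <- function(counts, nArtificial = 2L * ncol(.assayCounts(counts)),
                      seed = 0L, nHVG = 500L, nFolds = 4L,
                      nRounds = 120L, maxDepth = 4L, eta = 0.3) {
  counts <- .assayCounts(counts)
  n <- ncol(counts)
  if (n < 100L) stop("scoreBcds needs at least 100 cells")
  if (nArtificial < 1L) stop("nArtificial must be >= 1 (single-class training)")
  set.seed(seed)
  p1 <- sample.int(n, nArtificial, replace = TRUE)
  p2 <- sample.int(n, nArtificial, replace = TRUE)
  clash <- which(p1 == p2)
  while (length(clash)) {
    p2[clash] <- sample.int(n, length(clash), replace = TRUE)
    clash <- clash[p1[clash] == p2[clash]]
  }
  art <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  colnames(art) <- sprintf(".art%d", seq_len(nArtificial))
  combined <- cbind(counts, art)
  norm <- normalizeLog(combined)
  hvg <- selectHVG(norm, min(nHVG, nrow(norm)))
  X <- t(as.matrix(norm[hvg, , drop = FALSE]))
  y <- c(rep(0, n), rep(1, nArtificial))
  fold <- integer(n + nArtificial)
  fold[y == 0] <- sample(rep(seq_len(nFolds), length.out = n))
  fold[y == 1] <- sample(rep(seq_len(nFolds), length.out = nArtificial))
  pred <- numeric(n + nArtificial)
  params <- list(objective = "binary:logistic", max_depth = maxDepth,
                 eta = eta, nthread = 1, eval_metric = "logloss",
                 seed = seed)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("degenerate single-class training fold")
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    dte <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE])
    set.seed(seed + f)
    fit <- xgboost::xgb.train(params, dtr, nrounds = nRounds, verbose = 0)
    pred[!tr] <- predict(fit, dte)
  }
  setNames(pred[seq_len(n)], colnames(counts))
}

#' Combine cxds and bcds into the hybrid doublet score
#'
#' Each score is rank-normalized to \[0, 1\] (ties share the average rank)
#' and the two are averaged; the combined score inherits the strengths of
#' both detectors.
#'
#' @param cxds,bcds aligned per-cell score vectors.
#' @return per-cell hybrid score in \[0, 1\].
#' @export
combineHybridScore <- function(cxds, bcds) {
  if (length(cxds) != length(bcds))
    stop("cxds and bcds must have the same length")
  if (!is.null(names(cxds)) && !is.null(names(bcds)) &&
      !identical(names(cxds), names(bcds)))
    stop("cxds and bcds must be aligned on the same cells")
  out <- (.rankUnit(cxds) + .rankUnit(bcds)) / 2
  names(out) <- names(cxds)
  out
}

#' Score doublets with all three methods
#'
#' @param counts genes-by-cells count matrix or `SingleCellExperiment`.
#' @param nTopPairs passed to [scoreCxds()].
#' @param seed,... passed to [scoreBcds()].
#' @return `DataFrame` with columns `cxds`, `bcds`, `hybrid_score`, one row
#'   per cell.
#' @export
scoreDoublets <- function(counts, nTopPairs = 500L, seed = 0L, ...) {
  cx <- scoreCxds(counts, nTopPairs)
  bc <- scoreBcds(counts, seed = seed, ...)
  S4Vectors::DataFrame(cxds = cx, bcds = bc,
                       hybrid_score = combineHybridScore(cx, bc),
                       row.names = names(cx))
}

#' Derive the doublet-filter threshold
#'
#' `mean_plus_2sd` returns the sample mean plus twice the sample standard
#' deviation (n - 1 denominator) of the combined score; `fixed` returns the
#' supplied value (the published analysis used 0.5, which coincided with
#' mean + 2 SD on its data).
#'
#' @param scores per-cell hybrid scores (>= 2 cells for `mean_plus_2sd`).
#' @param method `"mean_plus_2sd"` or `"fixed"`.
#' @param fixedValue threshold value, required when `method = "fixed"`.
#' @return A [DoubletThreshold-class] object; read its cut point with
#'   [thresholdValue()].
#' @export
deriveThreshold <- function(scores, method = c("mean_plus_2sd", "fixed"),
                            fixedValue = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixedValue)) stop("method 'fixed' requires fixedValue")
    return(new("DoubletThreshold", method = "fixed", value = fixedValue,
               mean = NA_real_, sd = NA_real_))
  }
  if (length(scores) < 2L) stop("need at least 2 cells")
  m <- mean(scores)
  s <- sd(scores)
  new("DoubletThreshold", method = "mean_plus_2sd", value = m + 2 * s,
      mean = m, sd = s)
}
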