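# Doublet-vs-hybrid disambiguation: where would real droplet doublets land?
#
# If gated hybrid cells were epithelial x myeloid droplet doublets, their
# cluster placement should follow the placement of artificial doublets built
# from actual parent cells (close to 50/50 for balanced parents). A strong
# myeloid skew of the observed hybrids against that empirical null argues
# for genuine hybrids. A bimodality check on the doublet scores of gated
# cells looks for the small truly-doublet subpopulation.

# project count columns into a fitted reference map and assign each to the
# nearest cluster centroid
.assignToMap <- function(map, counts, ids) {
  sub <- counts[, ids, drop = FALSE]
  nrm <- normalizeLog(sub, map$target_sum)
  X <- t(as.matrix(nrm[map$hvg, , drop = FALSE]))
  X <- sweep(X, 2, map$center)
  proj <- X %*% map$rotation
  cn2 <- rowSums(map$centroids^2)
  d2 <- outer(rowSums(proj^2), cn2, "+") - 2 * proj %*% t(map$centroids)
  nearest <- rownames(map$centroids)[max.col(-d2, ties.method = "first")]
  data.frame(cell_id = if (is.character(ids)) ids else colnames(sub),
             cluster = as.integer(nearest),
             lineage = unname(map$cluster_lineage[nearest]),
             row.names = NULL)
}

#' Empirical placement null for artificial epithelial x myeloid doublets
#'
#' Builds a reference cluster map from the observed cells (normalize, HVG,
#' PCA, SNN clustering, majority-lineage annotation) — optionally excluding
#' the gated cells under scrutiny, so the map reflects the *parental*
#' population structure — then simulates `nSim` artificial doublets by
#' summing one epithelial and one myeloid parent, projects them with the
#' fitted PCA loadings (never refit, so the null lives in the observed
#' map), assigns each to its nearest cluster centroid, and reports the
#' fraction placed in myeloid-annotated clusters.
#'
#' @param counts genes-by-cells count matrix or `SingleCellExperiment` of
#'   observed cells.
#' @param cellTypes per-cell type labels used to annotate clusters (for
#'   simulated data use [annotateTruth()], which emulates an upstream
#'   annotation without hybrid/doublet categories).
#' @param epithelialIds,myeloidIds non-empty parent pools (cell ids or
#'   column indices).
#' @param nSim number of artificial doublets (a warning is issued below
#'   100; the null is unstable there).
#' @param config a [preprocessConfig()] for the embedding/clustering.
#' @param seed seed for parent sampling.
#' @param excludeIds cells excluded from the reference map fit (typically
#'   the gated hybrid candidates whose placement will be tested with
#'   [placeInNullMap()]); they are still projectable.
#' @return list with `null_fraction`, `mc_se` (binomial Monte-Carlo
#'   standard error), `n_sim`, `placed_lineage` (per-doublet lineage),
#'   `clusters`, `annotation`, `embedding`, and the projection `map` used
#'   by [placeInNullMap()].
#' @export
doubletAssignmentNull <- function(counts, cellTypes, epithelialIds,
                                  myeloidIds, nSim = 1000L,
                                  config = preprocessConfig(), seed = 0L,
                                  excludeIds = NULL) {
  counts <- .assayCounts(counts)
  if (length(epithelialIds) == 0L || length(myeloidIds) == 0L)
    stop("both parent pools must be non-empty")
  if (nSim < 100L) warning("nSim < 100 gives an unstable null")

  if (is.null(names(cellTypes))) names(cellTypes) <- colnames(counts)
  fitIds <- setdiff(colnames(counts), excludeIds)
  fitCounts <- counts[, fitIds, drop = FALSE]
  norm <- normalizeLog(fitCounts, config@targetSum)
  hvg <- selectHVG(norm, min(config@nHVG, nrow(norm)),
                   force = intersect(config@forceGenes, rownames(norm)))
  emb <- embedPCA(norm[hvg, , drop = FALSE], config@nPCs)
  cl <- clusterGraph(emb, config@knnK, config@resolution, config@seed)
  ann <- majorityAnnotation(cl, cellTypes[fitIds])
  clLineage <- setNames(lineageOf(ann$majority_type),
                        as.character(ann$cluster))
  centroids <- rowsum(emb, cl) / as.vector(table(cl))

  map <- list(hvg = hvg, center = attr(emb, "center"),
              rotation = attr(emb, "rotation"), centroids = centroids,
              cluster_lineage = clLineage,
              target_sum = config@targetSum)

  set.seed(seed)
  e <- sample(epithelialIds, nSim, replace = TRUE)
  m <- sample(myeloidIds, nSim, replace = TRUE)
  dbl <- counts[, e, drop = FALSE] + counts[, m, drop = FALSE]
  colnames(dbl) <- sprintf("sim%d", seq_len(nSim))
  placed <- .assignToMap(map, dbl, colnames(dbl))$lineage

  f <- mean(placed == "myeloid")
  list(null_fraction = f,
       mc_se = sqrt(f * (1 - f) / nSim),
       n_sim = as.integer(nSim),
       placed_lineage = placed,
       clusters = cl,
       annotation = ann,
       embedding = emb,
       map = map)
}

#' Place observed cells in the null's reference map
#'
#' Projects the given cells (e.g. the gated hybrid candidates) with the
#' PCA loadings fitted by [doubletAssignmentNull()] and assigns each to
#' its nearest cluster centroid — the identical measurement applied to the
#' artificial doublets, so observed and null placement fractions are
#' directly comparable in [testMyeloidSkew()].
#'
#' @param nullRes a [doubletAssignmentNull()] result.
#' @param counts the observed count matrix or `SingleCellExperiment`.
#' @param cellIds cells to place.
#' @return data.frame with columns `cell_id`, `cluster`, `lineage`.
#' @export
placeInNullMap <- function(nullRes, counts, cellIds) {
  .assignToMap(nullRes$map, .assayCounts(counts), cellIds)
}

#' Exact binomial test for myeloid placement skew
#'
#' Two-sided exact binomial test of the observed number of hybrid cells
#' placed in myeloid clusters against `Binomial(nHybrids, nullFraction)`,
#' computed by summing the probabilities of all outcomes no more probable
#' than the observed one.
#'
#' @param nHybrids number of gated hybrid cells.
#' @param nMyeloidPlaced number of those placed in myeloid-annotated
#'   clusters (`<= nHybrids`).
#' @param nullFraction null placement probability, strictly inside (0, 1)
#'   (use the [doubletAssignmentNull()] estimate, not an assumed 0.5).
#' @return An object of class `htest` with the exact two-sided `p.value`,
#'   the observed fraction as `estimate`, and the null fraction as
#'   `null.value`.
#' @export
testMyeloidSkew <- function(nHybrids, nMyeloidPlaced, nullFraction) {
  stopifnot(nMyeloidPlaced <= nHybrids, nHybrids >= 1)
  if (nullFraction <= 0 || nullFraction >= 1)
    stop("nullFraction must lie strictly inside (0, 1)")
  d <- dbinom(0:nHybrids, nHybrids, nullFraction)
  # relative tolerance guards against floating-point ties (as binom.test)
  p <- min(1, sum(d[d <= d[nMyeloidPlaced + 1L] * (1 + 1e-7)]))
  structure(list(
    statistic = c(myeloid_placed = nMyeloidPlaced),
    parameter = c(n_hybrids = nHybrids),
    p.value = p,
    estimate = c(observed_fraction = nMyeloidPlaced / nHybrids),
    null.value = c(null_fraction = nullFraction),
    alternative = "two.sided",
    method = "Exact two-sided binomial test of myeloid placement skew",
    data.name = sprintf("%d of %d hybrid cells in myeloid clusters",
                        nMyeloidPlaced, nHybrids)),
    class = "htest")
}

#' Bimodality check on doublet scores of gated cells
#'
#' Fits one- and two-component Gaussian mixtures (unequal variances) to the
#' combined doublet scores of gate-passing cells and reports the BIC
#' difference (two-component minus one-component, conventional
#' lower-is-better BIC). A difference below `deltaBICCutoff` (default -10,
#' strong evidence) yields the decision "bimodal", and the weight of the
#' high-score component estimates the truly-doublet contamination among
#' gated cells.
#'
#' @param scores hybrid doublet scores of gated cells (>= 20 values).
#' @param deltaBICCutoff decision cutoff on the BIC difference.
#' @return list with `delta_bic`, `decision` (`"bimodal"` /
#'   `"unimodal"`), `high_mode_weight`, `minor_weight`, `means`, and
#'   `regularized` (TRUE when a degenerate-variance fit required a prior).
#' @export
testBimodality <- function(scores, deltaBICCutoff = -10) {
  if (length(scores) < 20L) stop("need at least 20 cells")
  fit <- function(G, prior = NULL) {
    suppressWarnings(mclust::Mclust(scores, G = G, modelNames = "V",
                                    prior = prior, verbose = FALSE))
  }
  regularized <- FALSE
  m1 <- fit(1); m2 <- fit(2)
  if (is.null(m1) || is.null(m2) || is.na(m1$bic) || is.na(m2$bic) ||
      any(m2$parameters$variance$sigmasq < .Machine$double.eps)) {
    regularized <- TRUE
    pr <- mclust::priorControl()
    m1 <- fit(1, pr); m2 <- fit(2, pr)
    if (is.null(m1) || is.null(m2))
      stop("mixture fit failed even with regularization")
  }
  # mclust BIC is 2*loglik - npar*log(n) (higher better); convert to the
  # conventional -2*loglik + npar*log(n) scale before differencing
  deltaBIC <- (-m2$bic) - (-m1$bic)
  pro <- m2$parameters$pro
  mu <- m2$parameters$mean
  hi <- which.max(mu)
  list(delta_bic = as.numeric(deltaBIC),
       decision = if (deltaBIC < deltaBICCutoff) "bimodal" else "unimodal",
       high_mode_weight = pro[hi],
       minor_weight = min(pro),
       means = as.numeric(mu),
       regularized = regularized)
}
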