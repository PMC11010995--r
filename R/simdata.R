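# Synthetic scRNA-seq generator with ground-truth hybrids and doublets.
#
# Programs are relative mean-expression profiles per cell type; a cell's
# counts are NB draws around its library-size-scaled program. Hybrids use a
# convex epithelial/macrophage program mixture (weight lambda) plus
# hybrid-private up-regulated genes; doublets are exact sums of two singlets.

# integer apportionment of `total` across `weights` (largest remainder)
.apportion <- function(total, weights) {
  if (total <= 0 || sum(weights) == 0) return(integer(length(weights)))
  q <- total * weights / sum(weights)
  out <- floor(q)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(q - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

.geneNames <- function(config) {
  markers <- unlist(config@markerGenes, use.names = FALSE)
  private <- setdiff(names(config@hybridPrivateGenes), markers)
  named <- c(markers, private)
  nFill <- config@nGenes - length(named)
  c(named, sprintf("g%04d", seq_len(nFill)))
}

#' Type-by-gene mean expression programs
#'
#' Builds the relative mean-expression matrix underlying the simulator.
#' Marker genes take a fixed high mean in their owning lineage and a fixed
#' low mean elsewhere (the high/low ratio is far above the guaranteed
#' 10-fold enrichment); all other genes draw i.i.d. gamma means per type,
#' so types are separable beyond their markers.
#'
#' @param config a [simConfig()] object.
#' @return numeric matrix, rows = cell types, columns = genes.
#' @export
makePrograms <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  genes <- .geneNames(config)
  types <- names(config@cellsPerType)
  set.seed(config@seed)
  prog <- matrix(
    rgamma(length(types) * length(genes),
           shape = config@gammaShape, scale = config@gammaScale),
    nrow = length(types), dimnames = list(types, genes))
  for (lin in names(config@markerGenes)) {
    mk <- config@markerGenes[[lin]]
    owns <- lineageOf(types) == lin
    prog[, mk] <- config@markerLowMean
    if (any(owns)) prog[owns, mk] <- config@markerHighMean
  }
  prog
}

# NB counts for one population given a relative mean profile
.nbCounts <- function(n, profile, config, ids) {
  if (n == 0L) {
    m <- Matrix::Matrix(0, nrow = length(profile), ncol = 0, sparse = TRUE)
    rownames(m) <- names(profile)
    return(m)
  }
  lib <- rlnorm(n, config@libsizeMeanlog, config@libsizeSdlog)
  p <- profile / sum(profile)
  mu <- outer(p, lib)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config@nbDispersion),
                   nrow = length(p),
                   dimnames = list(names(profile), ids))
  as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

.hybridCounts <- function(lambda, prog, config) {
  stopifnot(all(c("epithelial", "macrophage") %in% rownames(prog)))
  n <- length(lambda)
  cols <- vector("list", n)
  priv <- config@hybridPrivateGenes
  for (i in seq_len(n)) {
    m <- lambda[i] * prog["epithelial", ] + (1 - lambda[i]) * prog["macrophage", ]
    m[names(priv)] <- m[names(priv)] * 2^priv
    cols[[i]] <- .nbCounts(1L, m, config, sprintf("tmp%d", i))
  }
  out <- do.call(cbind, cols)
  out
}

#' Simulate singlet and hybrid cells
#'
#' Draws negative-binomial counts for every singlet type in
#' `cellsPerType`, assigns each cell to a tumor or normal tissue fraction
#' (myeloid cells preferentially to tumor, so the tumor fraction reaches
#' `tumorMyeloidFrac` myeloid content against `normalMyeloidFrac` in
#' normal), and appends true hybrid cells whose expected expression is the
#' convex mixture `lambda * epithelial + (1 - lambda) * macrophage` with
#' hybrid-private genes up-regulated by their log2 effect.
#'
#' @param config a [simConfig()] object.
#' @param programs optional precomputed [makePrograms()] matrix.
#' @return A `SingleCellExperiment` with a sparse `counts` assay and
#'   ground-truth `colData` (see [simTruth()]).
#' @export
simulateCells <- function(config, programs = makePrograms(config)) {
  stopifnot(is(config, "SimConfig"))
  types <- names(config@cellsPerType)
  nPer <- config@cellsPerType
  nSing <- sum(nPer)
  if (nSing < 1L) stop("cellsPerType must include at least one cell")

  # --- tissue allocation -------------------------------------------------
  split <- config@tissueSplit
  isMye <- lineageOf(types) == "myeloid"
  wT <- split * config@tumorMyeloidFrac
  wN <- (1 - split) * config@normalMyeloidFrac
  myeTumorShare <- if (wT + wN > 0) wT / (wT + wN) else 0
  nTumType <- integer(length(types))
  nTumType[isMye] <- round(myeTumorShare * nPer[isMye])
  nTumTarget <- round(split * nSing)
  nTumNonMye <- min(max(nTumTarget - sum(nTumType[isMye]), 0L),
                    sum(nPer[!isMye]))
  nTumType[!isMye] <- .apportion(nTumNonMye, nPer[!isMye])
  nTumType <- pmin(nTumType, nPer)

  # --- singlet counts ----------------------------------------------------
  set.seed(config@seed + 1L)
  mats <- vector("list", length(types))
  tissue <- character(0)
  label <- character(0)
  for (i in seq_along(types)) {
    ids <- sprintf("%s_%04d", types[i], seq_len(nPer[i]))
    mats[[i]] <- .nbCounts(nPer[i], programs[types[i], ], config, ids)
    tissue <- c(tissue, rep(c("tumor", "normal"),
                            c(nTumType[i], nPer[i] - nTumType[i])))
    label <- c(label, rep(types[i], nPer[i]))
  }
  counts <- do.call(cbind, mats)
  lambda <- rep(NA_real_, nSing)

  # --- hybrids -----------------------------------------------------------
  hf <- config@hybridFraction
  if (length(hf) == 1L && is.null(names(hf))) hf <- c(tumor = hf, normal = hf)
  nTum <- sum(tissue == "tumor")
  nHyb <- c(tumor = round(hf[["tumor"]] * nTum),
            normal = round(hf[["normal"]] * (nSing - nTum)))
  if (sum(nHyb) > 0) {
    if (!all(c("epithelial", "macrophage") %in% rownames(programs)))
      stop("hybrid simulation requires epithelial and macrophage programs")
    lam <- runif(sum(nHyb), config@mixingWeightRange[1],
                 config@mixingWeightRange[2])
    hm <- .hybridCounts(lam, programs, config)
    colnames(hm) <- sprintf("hybrid_%04d", seq_len(ncol(hm)))
    counts <- cbind(counts, hm)
    tissue <- c(tissue, rep(c("tumor", "normal"), nHyb))
    label <- c(label, rep("hybrid", sum(nHyb)))
    lambda <- c(lambda, lam)
  }

  # --- assemble ----------------------------------------------------------
  sampleId <- character(length(tissue))
  for (tis in c("tumor", "normal")) {
    idx <- which(tissue == tis)
    k <- if (tis == "tumor") 4L else 2L
    sampleId[idx] <- sprintf("%s%d", ifelse(tis == "tumor", "T", "N"),
                             (seq_along(idx) - 1L) %% k + 1L)
  }
  cd <- S4Vectors::DataFrame(
    sample_id = sampleId, tissue = tissue, true_label = label,
    lambda = lambda, parent1 = NA_character_, parent2 = NA_character_,
    row.names = colnames(counts))
  SingleCellExperiment::SingleCellExperiment(list(counts = counts),
                                             colData = cd)
}

#' Inject droplet doublets
#'
#' Appends artificial droplet doublets whose count vectors are exact
#' elementwise sums of two sampled singlet cells, recording both parents in
#' the ground truth.
#'
#' @param sce a simulated `SingleCellExperiment`.
#' @param rate doublet proportion in \[0, 1): `round(rate * ncol(sce))`
#'   doublets are added.
#' @param seed integer seed.
#' @param parentMode `"uniform"` samples both parents uniformly from all
#'   singlets; `"epi_myeloid"` restricts to epithelial x monocyte/macrophage
#'   pairs (the heterotypic null used by the disambiguation module).
#' @return The extended `SingleCellExperiment`.
#' @export
injectDoublets <- function(sce, rate, seed = 0L,
                           parentMode = c("uniform", "epi_myeloid")) {
  parentMode <- match.arg(parentMode)
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(sce)
  truth <- simTruth(sce)
  singlets <- which(!truth$true_label %in% c("hybrid", "doublet"))
  if (length(singlets) < 2L) stop("need at least 2 singlet cells")
  nD <- round(rate * ncol(sce))
  if (nD == 0L) return(sce)
  set.seed(seed)
  if (parentMode == "epi_myeloid") {
    epi <- singlets[truth$true_label[singlets] == "epithelial"]
    mye <- singlets[lineageOf(truth$true_label[singlets]) == "myeloid"]
    if (length(epi) == 0L || length(mye) == 0L)
      stop("epi_myeloid mode needs both epithelial and myeloid singlets")
    p1 <- sample(epi, nD, replace = TRUE)
    p2 <- sample(mye, nD, replace = TRUE)
  } else {
    p1 <- sample(singlets, nD, replace = TRUE)
    p2 <- sample(singlets, nD, replace = TRUE)
    clash <- which(p1 == p2)
    while (length(clash)) {
      p2[clash] <- sample(singlets, length(clash), replace = TRUE)
      clash <- clash[p1[clash] == p2[clash]]
    }
  }
  counts <- .assayCounts(sce)
  dm <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  colnames(dm) <- sprintf("doublet_%04d", seq_len(nD))
  cd <- S4Vectors::DataFrame(
    sample_id = truth$sample_id[p1], tissue = truth$tissue[p1],
    true_label = "doublet", lambda = NA_real_,
    parent1 = colnames(sce)[p1], parent2 = colnames(sce)[p2],
    row.names = colnames(dm))
  newCounts <- cbind(counts, dm)
  SingleCellExperiment::SingleCellExperiment(
    list(counts = newCounts),
    colData = rbind(truth, cd))
}

#' Simulate a full benchmark dataset
#'
#' [simulateCells()] followed by [injectDoublets()] at the configured
#' doublet rate.
#'
#' @param config a [simConfig()] object.
#' @param parentMode passed to [injectDoublets()].
#' @return A `SingleCellExperiment` with ground-truth `colData`.
#' @export
simulateDataset <- function(config, parentMode = "uniform") {
  sce <- simulateCells(config)
  injectDoublets(sce, config@doubletRate, seed = config@seed + 2L,
                 parentMode = parentMode)
}

#' Emulated upstream cell-type annotation of simulated cells
#'
#' Real datasets come with cell-type annotations produced by pipelines that
#' have no "hybrid" or "doublet" category: a hybrid cell is labelled by its
#' transcriptionally dominant parent and a doublet by one of its parents.
#' This helper converts ground-truth labels into such an annotation so that
#' cluster majority-typing of synthetic data behaves like consuming a real
#' dataset's metadata.
#'
#' @param truth ground-truth `DataFrame` from [simTruth()].
#' @return character vector of emulated annotation labels.
#' @export
annotateTruth <- function(truth) {
  lab <- as.character(truth$true_label)
  hyb <- which(lab == "hybrid")
  lab[hyb] <- ifelse(truth$lambda[hyb] >= 0.5, "epithelial", "macrophage")
  dbl <- which(lab == "doublet")
  if (length(dbl))
    lab[dbl] <- lab[match(truth$parent1[dbl], rownames(truth))]
  lab
}

#' Simulate a low-plex spatial dataset
#'
#' Simulates cells as in [simulateCells()], restricts counts to a targeted
#' gene panel, and places cell centroids (in micrometers) either uniformly
#' over the field or in type-specific spatial niches.
#'
#' @param config a [simConfig()] object.
#' @param panel character vector of panel gene ids (subset of the simulated
#'   genes; must be non-empty).
#' @param field numeric `c(width, height)` of the imaged region in um.
#' @param mode `"niche"` (each true label gets a Gaussian spatial niche) or
#'   `"uniform"`.
#' @param nicheSd niche spread (um) in niche mode.
#' @return list with `table` (a spatial cell table: `cell_id`,
#'   `x_centroid`, `y_centroid`, `total_counts`, one column per panel gene)
#'   and `truth` (the ground-truth `DataFrame`).
#' @export
simulateSpatial <- function(config, panel, field = c(1000, 1000),
                            mode = c("niche", "uniform"), nicheSd = 60) {
  mode <- match.arg(mode)
  if (length(panel) == 0L) stop("panel must contain at least one gene")
  sce <- simulateCells(config)
  counts <- .assayCounts(sce)
  missing <- setdiff(panel, rownames(counts))
  if (length(missing))
    stop("panel genes not simulated: ", paste(missing, collapse = ", "))
  counts <- counts[panel, , drop = FALSE]
  n <- ncol(counts)
  truth <- simTruth(sce)

  set.seed(config@seed + 3L)
  if (mode == "uniform") {
    x <- runif(n, 0, field[1])
    y <- runif(n, 0, field[2])
  } else {
    labs <- unique(truth$true_label)
    cx <- runif(length(labs), 0.15 * field[1], 0.85 * field[1])
    cy <- runif(length(labs), 0.15 * field[2], 0.85 * field[2])
    names(cx) <- names(cy) <- labs
    x <- pmin(pmax(rnorm(n, cx[truth$true_label], nicheSd), 0), field[1])
    y <- pmin(pmax(rnorm(n, cy[truth$true_label], nicheSd), 0), field[2])
  }
  tab <- data.frame(
    cell_id = colnames(counts), x_centroid = x, y_centroid = y,
    total_counts = Matrix::colSums(counts),
    as.matrix(Matrix::t(counts)),
    row.names = NULL, check.names = FALSE)
  attr(tab, "genes") <- panel
  list(table = tab, truth = truth)
}
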