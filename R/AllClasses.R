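#' @import methods
#' @importFrom stats rnbinom rlnorm rgamma runif rnorm dbinom p.adjust
#'   prcomp quantile sd var wilcox.test setNames rbinom median mad
#' @importFrom utils read.csv write.csv head
#' @importFrom tools md5sum
#' @importFrom mclust Mclust mclustBIC priorControl
NULL

.LINEAGE_OF_TYPE <- c(
  epithelial = "epithelial",
  monocyte   = "myeloid",
  macrophage = "myeloid"
)

#' Map cell-type labels to lineages
#'
#' Types named `epithelial` map to the epithelial lineage, `monocyte` and
#' `macrophage` to the myeloid lineage; anything else maps to `other`.
#'
#' @param types character vector of type labels.
#' @return character vector of lineage labels (`epithelial`, `myeloid`,
#'   `other`).
#' @export
lineageOf <- function(types) {
  out <- unname(.LINEAGE_OF_TYPE[as.character(types)])
  out[is.na(out)] <- "other"
  out
}

# ---------------------------------------------------------------- SimConfig

#' @rdname simConfig
#' @export
setClass("SimConfig", representation(
  nGenes            = "integer",
  cellsPerType      = "integer",
  markerGenes       = "list",
  hybridFraction    = "numeric",
  doubletRate       = "numeric",
  mixingWeightRange = "numeric",
  hybridPrivateGenes = "numeric",
  nbDispersion      = "numeric",
  libsizeMeanlog    = "numeric",
  libsizeSdlog      = "numeric",
  tumorMyeloidFrac  = "numeric",
  normalMyeloidFrac = "numeric",
  tissueSplit       = "numeric",
  markerHighMean    = "numeric",
  markerLowMean     = "numeric",
  gammaShape        = "numeric",
  gammaScale        = "numeric",
  seed              = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- c(object@hybridFraction, object@doubletRate, object@tumorMyeloidFrac,
            object@normalMyeloidFrac, object@tissueSplit)
  if (any(prop < 0 | prop > 1))
    msg <- c(msg, "all proportions must lie in [0, 1]")
  mw <- object@mixingWeightRange
  if (length(mw) != 2L || mw[1] > mw[2] || mw[1] <= 0 || mw[2] >= 1)
    msg <- c(msg, "mixingWeightRange must be an interval strictly inside (0, 1)")
  mk <- object@markerGenes
  if (anyDuplicated(unlist(mk)))
    msg <- c(msg, "marker gene lists must be disjoint across lineages")
  if (!all(names(mk) %in% c("epithelial", "myeloid")))
    msg <- c(msg, "markerGenes must be named 'epithelial' and/or 'myeloid'")
  nReserved <- length(unlist(mk)) +
    length(setdiff(names(object@hybridPrivateGenes), unlist(mk)))
  if (object@nGenes < nReserved)
    msg <- c(msg, "nGenes must cover all marker and hybrid-private genes")
  if (is.null(names(object@cellsPerType)) || any(object@cellsPerType < 0))
    msg <- c(msg, "cellsPerType must be a named vector of nonnegative counts")
  if (length(msg)) msg else TRUE
})

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the simulator emulates: negative-binomial
#' counts for epithelial / monocyte / macrophage / other expression programs,
#' rare true hybrid cells drawn from a convex mixture of the epithelial and
#' macrophage programs (mixing weight `lambda`) with additional
#' hybrid-private up-regulated genes, droplet doublets formed by summing two
#' singlets, and a tumor/normal tissue split with myeloid infiltration
#' differing between fractions.
#'
#' @param nGenes number of genes.
#' @param cellsPerType named integer vector of singlet counts per cell type.
#'   Types named `epithelial`, `monocyte`, `macrophage` carry lineage
#'   markers; any other name is an unmarked background type.
#' @param markerGenes named list with elements `epithelial` and `myeloid`,
#'   each a character vector of marker gene ids (at least the EPCAM/KRT8-like
#'   and CD14/CD163-like defaults).
#' @param hybridFraction proportion of cells that are true hybrids. Either a
#'   single proportion applied to both tissue fractions, or a named vector
#'   `c(tumor = , normal = )` of per-tissue proportions.
#' @param doubletRate proportion of droplet doublets injected by
#'   [simulateDataset()].
#' @param mixingWeightRange interval strictly inside (0, 1) from which the
#'   hybrid epithelial mixing weight `lambda` is drawn uniformly.
#' @param hybridPrivateGenes named numeric vector: gene id -> log2 effect
#'   size of hybrid-private up-regulation (an SPP1-like signature present in
#'   hybrids but neither parent).
#' @param nbDispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param libsizeMeanlog,libsizeSdlog log-normal library-size parameters.
#' @param tumorMyeloidFrac,normalMyeloidFrac myeloid fraction of cells in
#'   the tumor and normal tissue fractions.
#' @param tissueSplit fraction of cells belonging to the tumor fraction.
#' @param markerHighMean,markerLowMean relative mean expression of a marker
#'   gene in its owning lineage and in all other lineages.
#' @param gammaShape,gammaScale gamma parameters for non-marker program
#'   means.
#' @param seed integer seed controlling all randomness of the generator.
#' @return A validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(cellsPerType = c(epithelial = 50, macrophage = 50),
#'                  nGenes = 200, seed = 1)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L,
                      cellsPerType = c(epithelial = 2000L, monocyte = 150L,
                                       macrophage = 400L, other = 2450L),
                      markerGenes = list(
                        epithelial = c("EPCAM", "KRT8", "KRT18", "KRT19"),
                        myeloid    = c("CD14", "CD163", "CD68", "PTPRC")),
                      hybridFraction = 0.01,
                      doubletRate = 0.05,
                      mixingWeightRange = c(0.3, 0.7),
                      hybridPrivateGenes = setNames(
                        rep(2, 20),
                        c("SPP1", "CD44", sprintf("HPG%02d", 3:20))),
                      nbDispersion = 0.2,
                      libsizeMeanlog = log(7500),
                      libsizeSdlog = 0.35,
                      tumorMyeloidFrac = 0.148,
                      normalMyeloidFrac = 0.024,
                      tissueSplit = 0.7,
                      markerHighMean = 15,
                      markerLowMean = 0.01,
                      gammaShape = 0.5,
                      gammaScale = 2,
                      seed = 1L) {
  new("SimConfig",
      nGenes = as.integer(nGenes),
      cellsPerType = setNames(as.integer(cellsPerType), names(cellsPerType)),
      markerGenes = markerGenes,
      hybridFraction = hybridFraction,
      doubletRate = doubletRate,
      mixingWeightRange = as.numeric(mixingWeightRange),
      hybridPrivateGenes = hybridPrivateGenes,
      nbDispersion = nbDispersion,
      libsizeMeanlog = libsizeMeanlog,
      libsizeSdlog = libsizeSdlog,
      tumorMyeloidFrac = tumorMyeloidFrac,
      normalMyeloidFrac = normalMyeloidFrac,
      tissueSplit = tissueSplit,
      markerHighMean = markerHighMean,
      markerLowMean = markerLowMean,
      gammaShape = gammaShape,
      gammaScale = gammaScale,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes;",
      sum(object@cellsPerType), "singlets (",
      paste(names(object@cellsPerType), object@cellsPerType,
            sep = "=", collapse = ", "), ")\n")
  cat("  hybridFraction:", paste(object@hybridFraction, collapse = "/"),
      " doubletRate:", object@doubletRate,
      " lambda ~ U(", object@mixingWeightRange[1], ",",
      object@mixingWeightRange[2], ")\n")
  cat("  seed:", object@seed, "\n")
  invisible(NULL)
})

# --------------------------------------------------------- PreprocessConfig

#' @rdname preprocessConfig
#' @export
setClass("PreprocessConfig", representation(
  targetSum  = "numeric",
  nHVG       = "integer",
  nPCs       = "integer",
  knnK       = "integer",
  resolution = "numeric",
  forceGenes = "character",
  seed       = "integer"
))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@targetSum <= 0) msg <- c(msg, "targetSum must be positive")
  if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
  if (object@nPCs < 1L) msg <- c(msg, "nPCs must be >= 1")
  if (object@knnK < 1L) msg <- c(msg, "knnK must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Preprocessing configuration
#'
#' Parameters of the normalization / dimension-reduction / clustering
#' contract: counts are library-size scaled to `targetSum` and
#' log1p-transformed, the `nHVG` most dispersed genes (plus `forceGenes`)
#' feed a PCA whose top `nPCs` components are clustered on a shared
#' nearest-neighbor graph by modularity community detection at the given
#' `resolution`.
#'
#' @param targetSum counts-per-cell scaling constant.
#' @param nHVG number of highly variable genes to retain.
#' @param nPCs number of principal components.
#' @param knnK number of nearest neighbors for the SNN graph.
#' @param resolution community-detection resolution.
#' @param forceGenes genes force-retained in the HVG set (the gate markers
#'   by default) when present in the matrix.
#' @param seed seed for the (stochastic) community detection.
#' @return A `PreprocessConfig` object.
#' @export
preprocessConfig <- function(targetSum = 1e4, nHVG = 2000L, nPCs = 10L,
                             knnK = 20L, resolution = 0.8,
                             forceGenes = c("EPCAM", "KRT8", "CD14", "CD163"),
                             seed = 0L) {
  new("PreprocessConfig", targetSum = targetSum, nHVG = as.integer(nHVG),
      nPCs = as.integer(nPCs), knnK = as.integer(knnK),
      resolution = resolution, forceGenes = forceGenes,
      seed = as.integer(seed))
}

setMethod("show", "PreprocessConfig", function(object) {
  cat("PreprocessConfig: targetSum", object@targetSum,
      "| nHVG", object@nHVG, "| nPCs", object@nPCs,
      "| knnK", object@knnK, "| resolution", object@resolution, "\n")
  invisible(NULL)
})

# --------------------------------------------------------- DoubletThreshold

#' @rdname deriveThreshold
#' @export
setClass("DoubletThreshold", representation(
  method = "character",
  value  = "numeric",
  mean   = "numeric",
  sd     = "numeric"
))

setValidity("DoubletThreshold", function(object) {
  msg <- character()
  if (!object@method %in% c("mean_plus_2sd", "fixed"))
    msg <- c(msg, "method must be 'mean_plus_2sd' or 'fixed'")
  if (object@method == "mean_plus_2sd" &&
      !isTRUE(all.equal(object@value, object@mean + 2 * object@sd)))
    msg <- c(msg, "value must equal mean + 2*sd for method 'mean_plus_2sd'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DoubletThreshold", function(object) {
  cat("DoubletThreshold [", object@method, "]: ", format(object@value),
      if (object@method == "mean_plus_2sd")
        sprintf(" (mean %.4g + 2 x sd %.4g)", object@mean, object@sd),
      "\n", sep = "")
  invisible(NULL)
})

#' @rdname deriveThreshold
#' @param object,x a `DoubletThreshold`.
#' @export
thresholdValue <- function(x) x@value

# ------------------------------------------------------------------ GateSpec

#' @rdname gateSpec
#' @export
setClass("GateSpec", representation(
  epithelialMarkers  = "character",
  myeloidMarkers     = "character",
  minCount           = "integer",
  applyDoubletFilter = "logical",
  threshold          = "ANY"
))

setValidity("GateSpec", function(object) {
  msg <- character()
  if (length(object@epithelialMarkers) == 0L ||
      length(object@myeloidMarkers) == 0L)
    msg <- c(msg, "both marker lists must be non-empty")
  if (object@minCount < 1L) msg <- c(msg, "minCount must be >= 1")
  if (object@applyDoubletFilter && !is(object@threshold, "DoubletThreshold"))
    msg <- c(msg, "applyDoubletFilter requires a DoubletThreshold")
  if (!is.null(object@threshold) && !is(object@threshold, "DoubletThreshold"))
    msg <- c(msg, "threshold must be a DoubletThreshold or NULL")
  if (length(msg)) msg else TRUE
})

#' Marker co-expression gate specification
#'
#' A hybrid-cell gate: a cell is called hybrid when its raw count is at
#' least `minCount` for every epithelial marker AND every myeloid marker,
#' and, when the doublet filter is active, its combined doublet score does
#' not exceed the threshold. The defaults reproduce the stringent
#' EPCAM > 0 & KRT8 > 0 & CD14 > 0 & CD163 > 0 gate.
#'
#' @param epithelialMarkers,myeloidMarkers non-empty character vectors of
#'   gene ids.
#' @param minCount positive integer detection threshold (1 means "> 0").
#' @param applyDoubletFilter logical; require the doublet score to be at or
#'   below the threshold.
#' @param threshold a [DoubletThreshold-class] (required when
#'   `applyDoubletFilter = TRUE`).
#' @return A `GateSpec` object.
#' @examples
#' gateSpec()  # the four-marker gate
#' @export
gateSpec <- function(epithelialMarkers = c("EPCAM", "KRT8"),
                     myeloidMarkers = c("CD14", "CD163"),
                     minCount = 1L,
                     applyDoubletFilter = FALSE,
                     threshold = NULL) {
  new("GateSpec", epithelialMarkers = epithelialMarkers,
      myeloidMarkers = myeloidMarkers, minCount = as.integer(minCount),
      applyDoubletFilter = applyDoubletFilter, threshold = threshold)
}

setMethod("show", "GateSpec", function(object) {
  cat("GateSpec: [",
      paste(object@epithelialMarkers, collapse = ", "), "] AND [",
      paste(object@myeloidMarkers, collapse = ", "), "] >= ",
      object@minCount, "\n", sep = "")
  if (object@applyDoubletFilter) {
    cat("  doublet filter: score <= ", format(object@threshold@value),
        " (", object@threshold@method, ")\n", sep = "")
  }
  invisible(NULL)
})

# -------------------------------------------------------------- HybridCallSet

#' @rdname callHybrids
#' @export
setClass("HybridCallSet", representation(
  isHybrid = "logical",
  gate     = "GateSpec"
))

setValidity("HybridCallSet", function(object) {
  if (is.null(names(object@isHybrid)))
    "isHybrid must be named by cell id"
  else TRUE
})

#' @rdname callHybrids
#' @param x a `HybridCallSet`.
#' @export
hybridIds <- function(x) names(x@isHybrid)[x@isHybrid]

#' @rdname callHybrids
#' @export
nHybrids <- function(x) sum(x@isHybrid)

#' @rdname callHybrids
#' @export
isHybrid <- function(x) x@isHybrid

#' @rdname callHybrids
#' @export
nTotal <- function(x) length(x@isHybrid)

setMethod("show", "HybridCallSet", function(object) {
  n <- length(object@isHybrid)
  k <- sum(object@isHybrid)
  cat(sprintf("HybridCallSet: %d / %d cells (%.3g%%) pass the gate\n",
              k, n, 100 * k / max(n, 1L)))
  show(object@gate)
  invisible(NULL)
})
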