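# Hybrid-cell calling by multi-marker co-expression gates.

.gateGenes <- function(gate) c(gate@epithelialMarkers, gate@myeloidMarkers)

.scoreVector <- function(scores) {
  if (is.null(scores)) return(NULL)
  if (is(scores, "DataFrame") || is.data.frame(scores)) {
    if (!"hybrid_score" %in% colnames(scores))
      stop("scores must contain a 'hybrid_score' column")
    setNames(as.numeric(scores$hybrid_score), rownames(scores))
  } else as.numeric(scores)
}

#' Call hybrid cells with a marker co-expression gate
#'
#' A cell is called hybrid iff its raw count is at least `minCount` for
#' EVERY epithelial marker and EVERY myeloid marker in the gate (a pure
#' conjunction, order-independent), and — when the gate carries a doublet
#' filter — its combined doublet score is less than or equal to the
#' threshold. Gating operates on raw counts, so calls are invariant under
#' normalization.
#'
#' @param counts genes-by-cells count matrix or `SingleCellExperiment`.
#' @param gate a [gateSpec()].
#' @param scores per-cell doublet scores (vector of `hybrid_score`, or the
#'   [scoreDoublets()] `DataFrame`); required when the gate applies the
#'   doublet filter.
#' @return A `HybridCallSet`; see [hybridIds()], [nHybrids()], [isHybrid()].
#' @examples
#' m <- matrix(c(1, 1, 1, 1,
#'               0, 1, 1, 1), nrow = 4,
#'             dimnames = list(c("EPCAM", "KRT8", "CD14", "CD163"),
#'                             c("hyb", "not")))
#' hybridIds(callHybrids(m, gateSpec()))
#' @export
callHybrids <- function(counts, gate = gateSpec(), scores = NULL) {
  stopifnot(is(gate, "GateSpec"))
  validObject(gate)
  counts <- .assayCounts(counts)
  genes <- .gateGenes(gate)
  missing <- setdiff(genes, rownames(counts))
  if (length(missing))
    stop("gate gene(s) not present in the matrix: ",
         paste(missing, collapse = ", "))
  sub <- counts[genes, , drop = FALSE]
  pass <- Matrix::colSums(sub >= gate@minCount) == length(genes)
  if (gate@applyDoubletFilter) {
    sv <- .scoreVector(scores)
    if (is.null(sv)) stop("doublet filter requires scores")
    if (length(sv) != ncol(counts))
      stop("scores must cover every cell")
    if (!is.null(names(sv)) && !is.null(colnames(counts)))
      sv <- sv[colnames(counts)]
    pass <- pass & (sv <= gate@threshold@value)
  }
  ids <- colnames(counts)
  if (is.null(ids)) ids <- sprintf("cell%d", seq_len(ncol(counts)))
  new("HybridCallSet", isHybrid = setNames(as.logical(pass), ids),
      gate = gate)
}

#' Relaxed two-marker hybrid gate
#'
#' The permissive variant: one epithelial and one myeloid marker (EPCAM and
#' CD163 in the published analysis), no doublet filter. Its call set always
#' contains the stringent multi-marker calls.
#'
#' @param counts genes-by-cells count matrix or `SingleCellExperiment`.
#' @param epithelialGene,myeloidGene single marker gene ids.
#' @return A `HybridCallSet`.
#' @export
callHybridsRelaxed <- function(counts, epithelialGene = "EPCAM",
                               myeloidGene = "CD163") {
  callHybrids(counts, gateSpec(epithelialMarkers = epithelialGene,
                               myeloidMarkers = myeloidGene,
                               minCount = 1L))
}

#' Summarize hybrid abundance by group
#'
#' Exact per-group cell counts, hybrid counts and fractions; groups with
#' zero hybrids are included.
#'
#' @param calls a `HybridCallSet`.
#' @param cells per-cell metadata (`data.frame`/`DataFrame`, rows aligned
#'   to the gated matrix, rownames = cell ids).
#' @param groupKey name of the grouping column (e.g. `"tissue"`,
#'   `"sample_id"`).
#' @return data.frame with columns `group`, `n_cells`, `n_hybrids`,
#'   `fraction` (`n_hybrids / n_cells` exactly).
#' @export
summarizeByGroup <- function(calls, cells, groupKey) {
  stopifnot(is(calls, "HybridCallSet"))
  cells <- as.data.frame(cells)
  if (!groupKey %in% colnames(cells))
    stop("unknown group key: ", groupKey)
  hyb <- isHybrid(calls)
  if (!is.null(rownames(cells)) && all(names(hyb) %in% rownames(cells))) {
    grp <- cells[names(hyb), groupKey]
  } else {
    if (nrow(cells) != length(hyb))
      stop("cells metadata does not cover every gated cell")
    grp <- cells[[groupKey]]
  }
  if (anyNA(grp[hyb])) stop("every hybrid cell needs group metadata")
  levs <- sort(unique(as.character(grp)))
  nCells <- vapply(levs, function(l) sum(grp == l, na.rm = TRUE), numeric(1))
  nHyb <- vapply(levs, function(l) sum(hyb & grp == l, na.rm = TRUE),
                 numeric(1))
  data.frame(group = levs, n_cells = as.integer(nCells),
             n_hybrids = as.integer(nHyb), fraction = nHyb / nCells,
             row.names = NULL)
}

#' Fold enrichment between two fractions
#'
#' `fracA / fracB`; e.g. the hybrid percentage in the tumor fraction over
#' the normal fraction (0.21 / 0.05 = 4.2 in the published colon data).
#'
#' @param fracA,fracB nonnegative fractions.
#' @return the ratio. When `fracB` is zero the result is `Inf` with
#'   attribute `infinite = TRUE` and a warning.
#' @export
enrichmentRatio <- function(fracA, fracB) {
  stopifnot(fracA >= 0, fracB >= 0)
  if (fracB == 0) {
    warning("denominator fraction is zero; ratio reported as infinite")
    return(structure(Inf, infinite = TRUE))
  }
  fracA / fracB
}

#' Cluster co-localization of hybrid calls
#'
#' Fraction of hybrid cells falling in clusters of each majority lineage
#' (epithelial / myeloid / other); fractions partition the hybrid set and
#' sum to 1.
#'
#' @param calls a `HybridCallSet`.
#' @param clusters integer cluster label per cell (named by cell, aligned
#'   to the gated matrix).
#' @param annotation cluster annotation from [majorityAnnotation()]
#'   (columns `cluster`, `majority_type`). Clusters absent from the
#'   annotation are counted under `other` with a warning.
#' @return data.frame with columns `lineage`, `n_hybrids`, `fraction`.
#' @export
clusterColocalization <- function(calls, clusters, annotation) {
  stopifnot(is(calls, "HybridCallSet"))
  hyb <- isHybrid(calls)
  if (!is.null(names(clusters)) && all(names(hyb) %in% names(clusters)))
    clusters <- clusters[names(hyb)]
  else if (length(clusters) != length(hyb))
    stop("every hybrid cell must be clustered")
  if (anyNA(clusters[hyb])) stop("every hybrid cell must be clustered")
  lin <- setNames(lineageOf(annotation$majority_type),
                  as.character(annotation$cluster))
  hcl <- as.character(clusters[hyb])
  unknown <- setdiff(unique(hcl), names(lin))
  if (length(unknown)) {
    warning("unannotated cluster(s) counted as 'other': ",
            paste(unknown, collapse = ", "))
    lin[unknown] <- "other"
  }
  levs <- c("epithelial", "myeloid", "other")
  placed <- factor(unname(lin[hcl]), levels = levs)
  tab <- table(placed)
  nh <- sum(tab)
  data.frame(lineage = levs, n_hybrids = as.integer(tab),
             fraction = if (nh > 0) as.numeric(tab) / nh else rep(NA_real_, 3),
             row.names = NULL)
}
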