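# In-situ spatial cell tables: IO, gating, viewer annotations,
# neighborhood composition.

.METACOLS <- c("cell_id", "x_centroid", "y_centroid", "total_counts",
               "cluster", "is_hybrid", "is_epithelial", "is_myeloid")

.spatialGenes <- function(table) {
  g <- attr(table, "genes")
  if (is.null(g)) g <- setdiff(colnames(table), .METACOLS)
  g
}

#' Read a spatial cell-feature directory
#'
#' Expects an MTX trio (`matrix.mtx`, `features.tsv`, `barcodes.tsv`) and a
#' `cells.csv` with `cell_id`, `x_centroid`, `y_centroid` (micrometers).
#' Counts are joined to centroids by cell id; a small fraction of
#' unmatched ids is dropped and reported via attribute `unmatched`, more
#' than 1% is an error.
#'
#' @param path directory path.
#' @return spatial cell table (`data.frame`): `cell_id`, `x_centroid`,
#'   `y_centroid`, `total_counts`, one column per panel gene; panel kept in
#'   attribute `genes`.
#' @export
readSpatialDir <- function(path) {
  m <- as(Matrix::readMM(file.path(path, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(path, "features.tsv"))
  colnames(m) <- readLines(file.path(path, "barcodes.tsv"))
  cells <- read.csv(file.path(path, "cells.csv"), stringsAsFactors = FALSE)
  need <- c("cell_id", "x_centroid", "y_centroid")
  missing <- setdiff(need, colnames(cells))
  if (length(missing))
    stop("cells table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(cells$x_centroid)) || any(!is.finite(cells$y_centroid)))
    stop("centroid coordinates must be finite")
  common <- intersect(cells$cell_id, colnames(m))
  unmatched <- union(setdiff(cells$cell_id, colnames(m)),
                     setdiff(colnames(m), cells$cell_id))
  total <- length(union(cells$cell_id, colnames(m)))
  if (length(unmatched) / total > 0.01)
    stop("more than 1% of cell ids do not match between matrix and cells ",
         "table (", length(unmatched), " of ", total, ")")
  cells <- cells[match(common, cells$cell_id), , drop = FALSE]
  m <- m[, common, drop = FALSE]
  tab <- data.frame(cell_id = cells$cell_id,
                    x_centroid = cells$x_centroid,
                    y_centroid = cells$y_centroid,
                    total_counts = Matrix::colSums(m),
                    as.matrix(Matrix::t(m)),
                    row.names = NULL, check.names = FALSE)
  attr(tab, "genes") <- rownames(m)
  attr(tab, "unmatched") <- unmatched
  tab
}

#' Write a spatial cell table as an MTX trio plus cells.csv
#'
#' Inverse of [readSpatialDir()]; round-trips losslessly.
#'
#' @param table spatial cell table.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSpatialDir <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- .spatialGenes(table)
  m <- Matrix::Matrix(t(as.matrix(table[, genes, drop = FALSE])),
                      sparse = TRUE)
  rownames(m) <- genes
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "features.tsv"))
  writeLines(table$cell_id, file.path(dir, "barcodes.tsv"))
  write.csv(table[, c("cell_id", "x_centroid", "y_centroid")],
            file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Apply a hybrid gate to spatial cells
#'
#' Classifies every cell: `is_hybrid` when all gate markers (epithelial AND
#' myeloid) are detected at `minCount`, `is_epithelial` when only the
#' epithelial markers all pass, `is_myeloid` when only the myeloid markers
#' all pass. The three flags are mutually exclusive. No doublet filter is
#' applied — in-situ segmentation already yields single cells.
#'
#' @param table spatial cell table.
#' @param gate a [gateSpec()].
#' @return list with `table` (input plus the three flag columns) and
#'   `summary` (per-class counts and fractions over all cells).
#' @export
gateSpatial <- function(table, gate = gateSpec()) {
  stopifnot(is(gate, "GateSpec"))
  panel <- .spatialGenes(table)
  missing <- setdiff(.gateGenes(gate), panel)
  if (length(missing))
    stop("gate gene(s) absent from the panel: ",
         paste(missing, collapse = ", "))
  passAll <- function(genes) {
    sub <- as.matrix(table[, genes, drop = FALSE])
    rowSums(sub >= gate@minCount) == length(genes)
  }
  epi <- passAll(gate@epithelialMarkers)
  mye <- passAll(gate@myeloidMarkers)
  table$is_hybrid <- epi & mye
  table$is_epithelial <- epi & !table$is_hybrid
  table$is_myeloid <- mye & !table$is_hybrid
  n <- nrow(table)
  cls <- c(hybrid = sum(table$is_hybrid),
           epithelial = sum(table$is_epithelial),
           myeloid = sum(table$is_myeloid))
  cls <- c(cls, other = n - sum(cls))
  list(table = table,
       summary = data.frame(class = names(cls), n = as.integer(cls),
                            fraction = as.numeric(cls) / n,
                            row.names = NULL))
}

.spatialGroup <- function(table) {
  ifelse(table$is_hybrid, "hybrid",
         ifelse(table$is_epithelial, "epithelial",
                ifelse(table$is_myeloid, "myeloid", "other")))
}

#' Export viewer annotations
#'
#' One row per cell with its gate class (`hybrid`, `epithelial`,
#' `myeloid`, `other`), in the two-column CSV format spatial viewers import
#' as cell groups.
#'
#' @param table gated spatial cell table (flags computed).
#' @param path optional CSV output path.
#' @return data.frame with columns `cell_id`, `group` (invisibly when
#'   written to `path`).
#' @export
exportAnnotations <- function(table, path = NULL) {
  if (!all(c("is_hybrid", "is_epithelial", "is_myeloid") %in%
           colnames(table)))
    stop("run gateSpatial() first (classification flags missing)")
  out <- data.frame(cell_id = table$cell_id, group = .spatialGroup(table),
                    row.names = NULL)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Neighborhood composition around hybrid cells
#'
#' For every hybrid cell, the class fractions (hybrid / epithelial /
#' myeloid / other) of all cells within `radius` micrometers, excluding the
#' cell itself. Isolated hybrids (no neighbor in radius) get `NA` fractions
#' and `isolated = TRUE`.
#'
#' @param table gated spatial cell table.
#' @param radius neighborhood radius in um (> 0).
#' @return data.frame with one row per hybrid cell: `cell_id`,
#'   `n_neighbors`, `frac_hybrid`, `frac_epithelial`, `frac_myeloid`,
#'   `frac_other`, `isolated`.
#' @export
neighborhoodComposition <- function(table, radius) {
  stopifnot(radius > 0)
  if (!"is_hybrid" %in% colnames(table))
    stop("run gateSpatial() first (classification flags missing)")
  grp <- .spatialGroup(table)
  hybIdx <- which(table$is_hybrid)
  x <- table$x_centroid
  y <- table$y_centroid
  r2 <- radius^2
  rows <- lapply(hybIdx, function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    nb <- which(d2 <= r2)
    nb <- nb[nb != i]
    n <- length(nb)
    if (n == 0L) {
      fr <- rep(NA_real_, 4)
    } else {
      tab <- table(factor(grp[nb],
                          levels = c("hybrid", "epithelial", "myeloid",
                                     "other")))
      fr <- as.numeric(tab) / n
    }
    data.frame(cell_id = table$cell_id[i], n_neighbors = n,
               frac_hybrid = fr[1], frac_epithelial = fr[2],
               frac_myeloid = fr[3], frac_other = fr[4],
               isolated = n == 0L, row.names = NULL)
  })
  do.call(rbind, rows)
}
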