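# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: per-cell loops, pair enumeration via combn(),
# split enumeration, and a gene-by-gene running-sum walk.

# per-cell loop over an AND gate
oracleGateCalls <- function(counts, epi, mye, minCount = 1L,
                            scores = NULL, threshold = NULL) {
  counts <- as.matrix(counts)
  out <- logical(ncol(counts))
  for (c in seq_len(ncol(counts))) {
    pass <- TRUE
    for (g in c(epi, mye)) {
      if (counts[g, c] < minCount) pass <- FALSE
    }
    if (!is.null(scores) && scores[c] > threshold) pass <- FALSE
    out[c] <- pass
  }
  names(out) <- colnames(counts)
  out
}

# exhaustive pair enumeration for the co-expression doublet score
oracleCxds <- function(counts, nTopPairs) {
  B <- (as.matrix(counts) > 0) * 1
  n <- ncol(B)
  p <- rowMeans(B)
  pairs <- utils::combn(nrow(B), 2)
  w <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    O <- sum(B[i, ] * B[j, ])
    E <- n * p[i] * p[j]
    w[k] <- (E - O) / sqrt(E * (1 - p[i] * p[j]) + 1e-8)
  }
  pos <- which(w > 0)
  if (length(pos) == 0L) return(setNames(numeric(n), colnames(B)))
  ord <- pos[order(-w[pos], pairs[1, pos], pairs[2, pos])]
  ord <- ord[seq_len(min(nTopPairs, length(ord)))]
  score <- numeric(n)
  for (k in ord) {
    i <- pairs[1, k]; j <- pairs[2, k]
    score <- score + w[k] * (B[i, ] * B[j, ])
  }
  setNames(score, colnames(B))
}

# exact two-sided Wilcoxon p by enumerating every n-choose-k group split
oracleWilcoxP <- function(a, b) {
  x <- c(a, b)
  nA <- length(a)
  splits <- utils::combn(length(x), nA)
  r <- rank(x)
  uObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  uAll <- apply(splits, 2, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
  lower <- mean(uAll <= uObs)
  upper <- mean(uAll >= uObs)
  min(1, 2 * min(lower, upper))
}

# step-by-step running-sum extremum for the enrichment score
oracleES <- function(stats, set, weightExp = 1) {
  ord <- order(-stats, names(stats))
  stats <- stats[ord]
  genes <- names(stats)
  inSet <- genes %in% set
  s <- sum(inSet)
  nm <- sum(abs(stats[inSet])^weightExp)
  run <- 0
  best <- 0
  for (g in seq_along(genes)) {
    if (inSet[g]) {
      run <- run + abs(stats[g])^weightExp / nm
    } else {
      run <- run - 1 / (length(genes) - s)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# O(n^2) neighborhood composition
oracleNeighborhood <- function(table, radius, groups) {
  hybIdx <- which(table$is_hybrid)
  res <- list()
  for (i in hybIdx) {
    fr <- c(hybrid = 0, epithelial = 0, myeloid = 0, other = 0)
    n <- 0
    for (j in seq_len(nrow(table))) {
      if (j == i) next
      d <- sqrt((table$x_centroid[j] - table$x_centroid[i])^2 +
                (table$y_centroid[j] - table$y_centroid[i])^2)
      if (d <= radius) {
        n <- n + 1
        fr[groups[j]] <- fr[groups[j]] + 1
      }
    }
    res[[length(res) + 1L]] <-
      c(n = n, if (n > 0) fr / n else rep(NA_real_, 4))
  }
  do.call(rbind, res)
}
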