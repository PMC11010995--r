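# End-to-end orchestration: simulate/read -> preprocess -> doublet scores ->
# gate -> disambiguate -> DE -> GSEA, with flat-file outputs and a JSON
# report. Every stage is independently re-runnable from the files the
# previous stage wrote.

#' Default pipeline configuration
#'
#' Nested list consumed by [runPipeline()]; any part can be overridden, or
#' the whole list loaded from YAML via [readPipelineConfig()]. The single
#' `seed` propagates to every stochastic stage. With
#' `replication_mode = TRUE` the gate uses the published four-marker set
#' with a fixed 0.5 doublet-score cutoff; otherwise the threshold is
#' mean + 2 SD of the combined score.
#'
#' @param seed global integer seed.
#' @return configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    version = "1.0",
    seed = as.integer(seed),
    replication_mode = FALSE,
    stages = c("simulate", "preprocess", "doublets", "gate",
               "disambiguate", "de", "gsea"),
    input = list(mtx_dir = NULL),
    sim = list(),
    preprocess = list(),
    doublets = list(n_top_pairs = 500L),
    gate = list(epithelial = c("EPCAM", "KRT8"),
                myeloid = c("CD14", "CD163"),
                min_count = 1L,
                doublet_filter = TRUE,
                threshold_mode = "mean_plus_2sd",
                fixed_value = 0.5),
    disambiguate = list(n_sim = 1000L),
    de = list(min_pct = 0.1, logfc_threshold = 0.25),
    gsea = list(gmt = NULL, n_perm = 1000L, min_size = 5L, max_size = 500L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values merge over [defaultPipelineConfig()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultPipelineConfig()
  merge <- function(b, u) {
    for (k in names(u)) {
      b[[k]] <- if (is.list(b[[k]]) && is.list(u[[k]]))
        merge(b[[k]], u[[k]]) else u[[k]]
    }
    b
  }
  merge(base, user)
}

# synthetic gene-set collection used when no GMT is supplied: the planted
# hybrid-private signature, both marker programs, and seeded random sets
.syntheticGeneSets <- function(genes, simCfg, seed) {
  sets <- list(
    HYBRID_PRIVATE = intersect(names(simCfg@hybridPrivateGenes), genes),
    EPITHELIAL_MARKERS = intersect(simCfg@markerGenes$epithelial, genes),
    MYELOID_MARKERS = intersect(simCfg@markerGenes$myeloid, genes))
  set.seed(seed)
  for (i in 1:5)
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(genes, 20)
  sets
}

#' Run the full hybrid-cell pipeline
#'
#' Executes the configured stages, writes each stage's outputs under
#' `outDir` (MTX + cells.csv, clusters.csv, doublet_scores.csv,
#' hybrid_calls.csv, summary CSVs, DE TSVs, gsea.tsv) and a machine-readable
#' `report.json` stamped with the config hash and seed. A stage failure
#' halts the run naming the stage. Given the same configuration and seed,
#' two runs produce byte-identical reports.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outDir run directory (created).
#' @return the report, invisibly.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- config$stages
  report <- list(schema_version = "1.0", seed = seed, stages = list())
  configPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, configPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  report$config_hash <- unname(tools::md5sum(configPath))

  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sce <- NULL
  simCfg <- NULL

  if ("simulate" %in% stages) {
    runStage("simulate", {
      simCfg <- do.call(simConfig, c(config$sim, list(seed = seed)))
      sce <- simulateDataset(simCfg)
      writeCountsMTX(sce, file.path(outDir, "matrix"))
      report$stages$simulate <- list(
        n_cells = ncol(sce), n_genes = nrow(sce),
        n_hybrids_true = sum(sce$true_label == "hybrid"),
        n_doublets_true = sum(sce$true_label == "doublet"))
    })
  } else if (!is.null(config$input$mtx_dir)) {
    runStage("input", {
      sce <- readCountsMTX(config$input$mtx_dir)
      report$stages$input <- list(n_cells = ncol(sce), n_genes = nrow(sce))
    })
  } else stop("stage 'input' failed: no input matrix and simulate disabled")

  truth <- simTruth(sce)
  hasTruth <- "true_label" %in% colnames(truth)

  if ("preprocess" %in% stages) {
    runStage("preprocess", {
      ppCfg <- do.call(preprocessConfig,
                       c(config$preprocess, list(seed = seed)))
      sce <- preprocessCells(sce, ppCfg)
      write.csv(data.frame(cell_id = colnames(sce), cluster = sce$cluster),
                file.path(outDir, "clusters.csv"), row.names = FALSE)
      report$stages$preprocess <- list(
        n_clusters = length(unique(sce$cluster)),
        n_hvg = length(S4Vectors::metadata(sce)$hvg))
    })
  }

  scores <- NULL
  if ("doublets" %in% stages) {
    runStage("doublets", {
      scores <- scoreDoublets(sce, nTopPairs = config$doublets$n_top_pairs,
                               seed = seed)
      write.csv(cbind(cell_id = rownames(scores), as.data.frame(scores)),
                file.path(outDir, "doublet_scores.csv"), row.names = FALSE)
      report$stages$doublets <- list(
        median_hybrid_score = median(scores$hybrid_score))
    })
  }

  calls <- NULL
  if ("gate" %in% stages) {
    runStage("gate", {
      gcfg <- config$gate
      if (isTRUE(config$replication_mode)) {
        gcfg$threshold_mode <- "fixed"
        gcfg$fixed_value <- 0.5
      }
      useFilter <- isTRUE(gcfg$doublet_filter) && !is.null(scores)
      thr <- if (useFilter) {
        if (gcfg$threshold_mode == "fixed")
          deriveThreshold(method = "fixed", fixedValue = gcfg$fixed_value)
        else deriveThreshold(scores$hybrid_score, "mean_plus_2sd")
      } else NULL
      gate <- gateSpec(gcfg$epithelial, gcfg$myeloid, gcfg$min_count,
                       applyDoubletFilter = useFilter, threshold = thr)
      calls <- callHybrids(sce, gate, scores)
      write.csv(data.frame(cell_id = names(isHybrid(calls)),
                           is_hybrid = unname(isHybrid(calls))),
                file.path(outDir, "hybrid_calls.csv"), row.names = FALSE)
      st <- list(n_hybrid_calls = nHybrids(calls),
                 fraction = nHybrids(calls) / nTotal(calls))
      if (useFilter) st$threshold <- thr@value
      if ("tissue" %in% colnames(truth)) {
        bt <- summarizeByGroup(calls, truth, "tissue")
        write.csv(bt, file.path(outDir, "summary_by_tissue.csv"),
                  row.names = FALSE)
        ft <- bt$fraction[bt$group == "tumor"]
        fn <- bt$fraction[bt$group == "normal"]
        if (length(ft) && length(fn) && fn > 0)
          st$tumor_normal_enrichment <- as.numeric(ft / fn)
      }
      if (hasTruth && !is.null(sce$cluster)) {
        ann <- majorityAnnotation(sce$cluster, annotateTruth(truth))
        coloc <- clusterColocalization(calls, setNames(sce$cluster,
                                                       colnames(sce)), ann)
        write.csv(coloc, file.path(outDir, "colocalization.csv"),
                  row.names = FALSE)
        st$myeloid_placement <-
          coloc$fraction[coloc$lineage == "myeloid"]
        isTrueHyb <- truth$true_label == "hybrid"
        st$hybrid_recall <- sum(isHybrid(calls) & isTrueHyb) /
          max(sum(isTrueHyb), 1L)
        st$hybrid_precision <- if (nHybrids(calls) > 0)
          sum(isHybrid(calls) & isTrueHyb) / nHybrids(calls) else NA_real_
      }
      report$stages$gate <- st
    })
  }

  if ("disambiguate" %in% stages && hasTruth && !is.null(calls)) {
    runStage("disambiguate", {
      epi <- colnames(sce)[truth$true_label == "epithelial"]
      mye <- colnames(sce)[lineageOf(truth$true_label) == "myeloid"]
      nullRes <- doubletAssignmentNull(
        sce, annotateTruth(truth), epi, mye,
        nSim = config$disambiguate$n_sim,
        config = do.call(preprocessConfig,
                         c(config$preprocess, list(seed = seed))),
        seed = seed,
        excludeIds = hybridIds(calls))
      placed <- if (nHybrids(calls) > 0)
        placeInNullMap(nullRes, sce, hybridIds(calls)) else NULL
      k <- sum(placed$lineage == "myeloid")
      n <- if (is.null(placed)) 0L else nrow(placed)
      nf <- min(max(nullRes$null_fraction, 1e-6), 1 - 1e-6)
      skew <- if (n > 0) testMyeloidSkew(n, k, nf) else NULL
      gatedScores <- scores$hybrid_score[isHybrid(calls)]
      bim <- if (length(gatedScores) >= 20)
        testBimodality(gatedScores) else NULL
      report$stages$disambiguate <- list(
        null_fraction = nullRes$null_fraction,
        mc_se = nullRes$mc_se,
        observed_fraction = if (n > 0) k / n else NA,
        skew_p_value = if (!is.null(skew)) skew$p.value else NA,
        delta_bic = if (!is.null(bim)) bim$delta_bic else NA,
        bimodal = if (!is.null(bim)) bim$decision else NA)
      jsonlite::write_json(report$stages$disambiguate,
                           file.path(outDir, "disambiguate.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  de <- NULL
  if ("de" %in% stages && hasTruth && !is.null(calls)) {
    runStage("de", {
      norm <- SummarizedExperiment::assay(sce, "logcounts")
      hybIds <- hybridIds(calls)
      comps <- list(
        hybrid_vs_epithelial =
          setdiff(colnames(sce)[truth$true_label == "epithelial"], hybIds),
        hybrid_vs_myeloid =
          setdiff(colnames(sce)[lineageOf(truth$true_label) == "myeloid"],
                  hybIds))
      deStats <- list()
      for (nm in names(comps)) {
        if (length(hybIds) < 3L || length(comps[[nm]]) < 3L) next
        tab <- findMarkerGenes(norm, hybIds, comps[[nm]],
                               minPct = config$de$min_pct,
                               logfcThreshold = config$de$logfc_threshold)
        tab <- volcanoTable(tab)
        writeDETable(tab, file.path(outDir, paste0("de_", nm, ".tsv")))
        deStats[[nm]] <- list(n_tested = nrow(tab),
                              n_significant = sum(tab$significant))
        if (nm == "hybrid_vs_myeloid") de <- tab
      }
      report$stages$de <- deStats
    })
  }

  if ("gsea" %in% stages && !is.null(de)) {
    runStage("gsea", {
      sets <- if (!is.null(config$gsea$gmt)) readGMT(config$gsea$gmt)
      else .syntheticGeneSets(rownames(sce), simCfg, seed)
      res <- prerankedGSEA(rankFromDE(de), sets,
                           nPerm = config$gsea$n_perm,
                           minSize = config$gsea$min_size,
                           maxSize = config$gsea$max_size, seed = seed)
      utils::write.table(res, file.path(outDir, "gsea.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$stages$gsea <- list(
        n_sets = nrow(res),
        n_significant = sum(res$p_adj < 0.05),
        top_pathway = if (nrow(res)) res$pathway[1] else NA)
    })
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
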