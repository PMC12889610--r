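#' Default end-to-end run configuration
#'
#' Assembles a complete [runPipeline()] configuration around the default
#' synthetic study conditions (see [groundTruthConfig()]) with the
#' library-gated acquisition mode. Every stage's parameters are exposed and
#' the global seed deterministically derives the per-stage sub-seeds. By
#' default the rare granulocyte-like type (the last type) is excluded from
#' the reference, mirroring a blood-atlas reference that does not contain a
#' contaminating population.
#'
#' @param seed global seed.
#' @param nBatches batches to simulate.
#' @param outdir optional output directory for stage TSV/JSON files.
#' @return a `RunConfig` list.
#' @export
defaultRunConfig <- function(seed = 17L, nBatches = 20L, outdir = NULL) {
  truth <- groundTruthConfig(nBatches = nBatches,
                             seed = stageSeed(seed, "truth"))
  lastType <- sprintf("T%d", truth$nCellTypes)
  list(seed = as.integer(seed), outdir = outdir,
       synthetic = list(
         truth = truth,
         acquisition = acquisitionConfig(mode = "rtls",
                                         seed = stageSeed(seed, "acq")),
         reference = list(overlapFraction = 0.6, nRefCells = 500L,
                          excludeTypes = lastType,
                          seed = stageSeed(seed, "ref"))),
       normalize = list(minObsRate = 0.3, imputeK = 5L,
                        imputeMethod = "knn"),
       map = list(nHvp = 600L, k = 20L, nPcs = 30L),
       annotate = list(nHvp = 600L, nPcs = 30L, kNeighbors = 20L,
                       prune = 1 / 15, resolution = 1,
                       alpha = 0.05, mtMethod = "BH",
                       rMax = 0.67, pThresh = 0.01),
       de = list(minObs = 10L))
}

#' Run the full single-cell proteomics pipeline
#'
#' Executes the stages end-to-end: acquisition simulation (or user data),
#' QC with per-cell input estimation, median normalization, empirical-Bayes
#' batch correction, imputation, reference label transfer, a first
#' clustering + enrichment annotation pass, permeabilized-cluster flagging
#' and removal, a second annotation pass on the retained cells (highly
#' variable features re-selected), and one-vs-rest moderated-t differential
#' abundance on the non-imputed corrected data. When the run is synthetic,
#' ground-truth metrics (annotation accuracy on retained cells, recall of
#' planted permeabilized cells, marker ranking) are added to the report.
#'
#' @param config a `RunConfig` from [defaultRunConfig()] (possibly edited),
#'   or a path to a JSON file with the same structure.
#' @return a `RunReport` list with per-stage outputs (`truth`, `qm`,
#'   `qc`, `normalized`, `imputed`, `scores`, `annotation`,
#'   `permeabilization`, `annotation2`, `de`) and a `summary` list of
#'   headline metrics.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  t0 <- Sys.time()

  # --- simulate (or load) ---------------------------------------------
  if (!is.null(config$synthetic)) {
    truthCfg <- config$synthetic$truth
    if (!inherits(truthCfg, "GroundTruthConfig"))
      truthCfg <- do.call(groundTruthConfig, truthCfg)
    truth <- generateTruth(truthCfg)
    acqCfg <- config$synthetic$acquisition
    if (!inherits(acqCfg, "AcquisitionConfig"))
      acqCfg <- do.call(acquisitionConfig, acqCfg)
    sim <- simulateAcquisition(truth, acqCfg)
    qmPep <- sim$qm
    idSets <- sim$idSets
    design <- truth$design
    meta <- truth$samples
    refArgs <- config$synthetic$reference
    reference <- generateReference(
      truth, overlapFraction = refArgs$overlapFraction %||% 0.6,
      nRefCells = refArgs$nRefCells %||% 500L,
      seed = refArgs$seed %||% stageSeed(config$seed, "ref"),
      excludeTypes = refArgs$excludeTypes)
    logmsg("simulate: %d peptides x %d samples, %d runs",
           nrow(qmPep), ncol(qmPep), length(idSets))
  } else {
    paths <- config$input
    meta <- readSampleMeta(paths$meta)
    qmPep <- readQuantTable(paths$matrix, level = paths$level %||% "peptide",
                            sampleMeta = meta)
    design <- readPlexDesign(paths$design)
    reference <- paths$reference
    truth <- NULL
    idSets <- NULL
  }
  bundle <- validateDesign(design, meta, qmPep, requireBridge = TRUE)
  if (bundle$roleCounts[["single_cell"]] == 0L)
    stop("design contains zero single-cell channels")

  # --- qc --------------------------------------------------------------
  qmProt <- if (featureLevel(qmPep) == "peptide") aggregateProteins(qmPep)
            else qmPep
  cs <- channelSums(qmProt)
  # each ratio computed independently: all-missing blank channels (zero
  # median) must not void the bridge/cell fold
  folds <- list(
    bridge_vs_cell = tryCatch(
      foldDifferences(cs[cs$role != "blank", ])$bridge_vs_cell,
      error = function(e) NA_real_),
    cell_vs_blank = tryCatch(foldDifferences(cs)$cell_vs_blank,
                             error = function(e) NA_real_))
  cs <- estimateInput(cs, design)
  cellIds <- cs$sample_id[cs$role == "single_cell" & !cs$all_missing]
  comp <- completeness(qmProt, cellIds)
  curve <- if (!is.null(idSets))
    sensitivityCurve(idSets, nPerm = 100L,
                     seed = stageSeed(config$seed, "curve")) else NULL
  qc <- list(channelSummary = cs, folds = folds, completeness = comp,
             sensitivity = curve)
  logmsg("qc: completeness %.2f, median input %.1f pg", comp,
         stats::median(cs$est_input_pg[cs$role == "single_cell"],
                       na.rm = TRUE))

  # --- normalize -------------------------------------------------------
  ncfg <- config$normalize
  qmCells <- toLog2(qmProt[, cellIds])
  qmNorm <- medianNormalize(qmCells)
  cb <- combatAdjust(qmNorm, allowSingle = TRUE)
  qmCorr <- cb$qm
  qmImp <- imputeMissing(qmCorr, method = ncfg$imputeMethod %||% "knn",
                         k = ncfg$imputeK %||% 5L,
                         minObsRate = ncfg$minObsRate %||% 0.3,
                         seed = stageSeed(config$seed, "impute"))
  logmsg("normalize: %d/%d proteins pass the observation floor",
         nrow(qmImp), nrow(qmCorr))

  # --- map -------------------------------------------------------------
  mcfg <- config$map
  qmCorrKept <- qmCorr[rownames(qmImp), ]
  hvp <- selectHVF(qmCorrKept, min(mcfg$nHvp %||% 600L,
                                   nrow(qmCorrKept)))
  refExpr <- if (inherits(reference, "ReferenceExpression"))
    reference$expr else reference
  refVar <- apply(refExpr, 1L, stats::var)
  nHvg <- min(mcfg$nHvg %||% 2000L, nrow(refExpr))
  hvg <- rownames(refExpr)[order(-refVar,
                                 rownames(refExpr))][seq_len(nHvg)]
  ov <- featureOverlap(hvp, hvg)
  if (!ov$count)
    stop("no overlap between highly variable proteins and reference genes")
  scores <- transferLabels(qmImp, reference, shared = ov$shared,
                           k = mcfg$k %||% 20L, nPcs = mcfg$nPcs %||% 30L)
  logmsg("map: %d shared features, cutoff %.3f, %d/%d high confidence",
         ov$count, scoreCutoff(scores), sum(highConfidence(scores)),
         ncol(qmImp))

  # --- annotate pass 1 -------------------------------------------------
  acfg <- config$annotate
  annotatePass <- function(qmImpPass, qmCorrPass, scoresPass, tag) {
    hv <- selectHVF(qmCorrPass, min(acfg$nHvp %||% 600L,
                                    nrow(qmCorrPass)))
    hv <- intersect(hv, rownames(qmImpPass))
    emb <- pcaEmbed(qmImpPass, hv,
                    nPcs = min(acfg$nPcs %||% 30L, length(hv),
                               ncol(qmImpPass) - 1L))
    g <- snnGraph(emb, k = acfg$kNeighbors %||% 20L,
                  prune = acfg$prune %||% 1 / 15)
    cl <- louvainCluster(g, resolution = acfg$resolution %||% 1,
                         seed = stageSeed(config$seed,
                                          paste0("louvain-", tag)))
    ann <- clusterEnrichment(cl$clusters, scoresPass,
                             alpha = acfg$alpha %||% 0.05,
                             mtMethod = acfg$mtMethod %||% "BH")
    list(embedding = emb, graph = g, clustering = cl, annotation = ann)
  }
  pass1 <- annotatePass(qmImp, qmCorrKept, scores, "pass1")
  logmsg("annotate pass 1: %d clusters",
         length(unique(cellClusters(pass1$annotation))))

  # --- permeabilization filter ----------------------------------------
  perm <- flagPermeabilized(pass1$annotation, cs, scores,
                            rMax = acfg$rMax %||% 0.67,
                            pThresh = acfg$pThresh %||% 0.01)
  retained <- setdiff(colnames(qmImp), perm$flaggedCells)
  logmsg("permeabilization: %d cluster(s) flagged, %d cells removed",
         length(perm$flaggedClusters), length(perm$flaggedCells))

  # --- annotate pass 2 on retained cells ------------------------------
  scores2 <- predictionScores(scoreMatrix(scores)[retained, ,
                                                  drop = FALSE])
  pass2 <- annotatePass(qmImp[, retained], qmCorrKept[, retained],
                        scores2, "pass2")
  labels <- cellLabels(pass2$annotation)
  logmsg("annotate pass 2: %d clusters, labels: %s",
         length(unique(cellClusters(pass2$annotation))),
         paste(sprintf("%s=%d", names(table(labels)), table(labels)),
               collapse = ", "))

  # --- differential abundance -----------------------------------------
  de <- runDifferentialAbundance(qmCorr[, retained], labels,
                                 minObs = config$de$minObs %||% 10L)

  summary <- list(
    n_cells = length(cellIds), n_retained = length(retained),
    n_flagged = length(perm$flaggedCells),
    completeness = comp,
    median_input_pg = stats::median(
      cs$est_input_pg[cs$role == "single_cell"], na.rm = TRUE),
    fold_bridge_vs_cell = folds$bridge_vs_cell,
    fold_cell_vs_blank = folds$cell_vs_blank,
    n_proteins_quantified = nrow(qmImp),
    labels = as.list(table(labels)))

  if (!is.null(truth)) {
    trueType <- stats::setNames(truth$cells$type, truth$cells$sample_id)
    summary$annotation_accuracy <-
      mean(labels == trueType[names(labels)])
    planted <- truth$cells$sample_id[truth$cells$permeabilized]
    planted <- intersect(planted, cellIds)
    summary$perm_recall <- if (length(planted))
      mean(planted %in% perm$flaggedCells) else NA_real_
    summary$marker_top_decile <- markerTopDecile(de, truth)
  }

  report <- list(config = config, truth = truth, qm = qmPep,
                 qmProtein = qmProt, qc = qc, normalized = qmCorr,
                 batchModel = cb$model, imputed = qmImp, hvp = hvp,
                 overlap = ov, scores = scores, pass1 = pass1,
                 permeabilization = perm, pass2 = pass2, labels = labels,
                 de = de, summary = summary,
                 elapsed = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")))
  class(report) <- "RunReport"
  if (!is.null(config$outdir)) writeRunReport(report, config$outdir)
  report
}

# Fraction of planted (type, marker protein) pairs ranking in the top
# decile of moderated t within their own one-vs-rest contrast.
markerTopDecile <- function(de, truth) {
  hits <- 0L; tot <- 0L
  for (ty in unique(de$contrast)) {
    sub <- de[de$contrast == ty, ]
    markers <- truth$proteins$protein_id[
      !is.na(truth$proteins$marker_type) &
        truth$proteins$marker_type == ty]
    markers <- intersect(markers, sub$protein)
    if (!length(markers)) next
    cut <- stats::quantile(sub$t, 0.9, names = FALSE)
    hits <- hits + sum(sub$t[match(markers, sub$protein)] >= cut)
    tot <- tot + length(markers)
  }
  if (tot == 0L) NA_real_ else hits / tot
}

#' @export
print.RunReport <- function(x, ...) {
  s <- x$summary
  cat("RunReport\n")
  cat(sprintf("  cells: %d analyzed, %d retained, %d flagged permeabilized\n",
              s$n_cells, s$n_retained, s$n_flagged))
  cat(sprintf("  completeness %.2f | median input %.1f pg | %d proteins\n",
              s$completeness, s$median_input_pg,
              s$n_proteins_quantified))
  cat(sprintf("  folds: bridge/cell %.1f, cell/blank %.1f\n",
              s$fold_bridge_vs_cell, s$fold_cell_vs_blank))
  cat("  labels:", paste(sprintf("%s=%d", names(s$labels),
                                 unlist(s$labels)), collapse = ", "), "\n")
  if (!is.null(s$annotation_accuracy))
    cat(sprintf("  truth: accuracy %.3f | perm recall %.3f | markers top-decile %.3f\n",
                s$annotation_accuracy, s$perm_recall,
                s$marker_top_decile))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Write the tabular outputs of a pipeline run
#'
#' Emits the stage outputs as plain TSV/JSON under `dir`: the peptide and
#' protein matrices, channel summary, normalized/imputed matrices,
#' prediction scores, cluster/enrichment/label tables, the
#' permeabilization report, differential-abundance results and the summary
#' JSON.
#'
#' @param report a `RunReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeQuantTable(report$qm, fp("peptide_matrix.tsv"))
  writeQuantTable(report$qmProtein, fp("protein_matrix.tsv"))
  writeSampleMeta(as.data.frame(colData(report$qm)), fp("sample_meta.tsv"))
  utils::write.table(report$qc$channelSummary, fp("channel_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$qc$folds, fp("folds.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeQuantTable(report$normalized, fp("normalized_matrix.tsv"))
  writeQuantTable(report$imputed, fp("imputed_matrix.tsv"))
  utils::write.table(
    data.frame(cell = rownames(scoreMatrix(report$scores)),
               scoreMatrix(report$scores),
               max_score = maxScores(report$scores),
               predicted = predictedType(report$scores),
               high_confidence = highConfidence(report$scores),
               check.names = FALSE),
    fp("prediction_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ann <- report$pass2$annotation
  utils::write.table(
    data.frame(cell = names(cellClusters(ann)),
               cluster = cellClusters(ann),
               label = cellLabels(ann)),
    fp("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enrichmentTable(ann), fp("enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$permeabilization$report))
    utils::write.table(report$permeabilization$report,
                       fp("permeabilization_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(report$de, fp("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$summary, fp("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}
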