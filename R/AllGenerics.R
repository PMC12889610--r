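#' Accessors for QuantMatrix
#'
#' `intensities()` returns the intensity matrix (NA = missing),
#' `missingMask()` the logical missingness mask, `featureLevel()` and
#' `intensityScale()` the level/scale tags, and `sampleRoles()` the per-sample
#' role vector (if present in `colData`).
#'
#' @param x a [QuantMatrix-class]
#' @return see the individual descriptions.
#' @name QuantMatrix-accessors
#' @aliases intensities missingMask featureLevel intensityScale sampleRoles
NULL

#' @rdname QuantMatrix-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname QuantMatrix-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname QuantMatrix-accessors
#' @export
setGeneric("featureLevel", function(x) standardGeneric("featureLevel"))

#' @rdname QuantMatrix-accessors
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname QuantMatrix-accessors
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname QuantMatrix-accessors
setMethod("intensities", "QuantMatrix", function(x) assay(x, "intensity"))

#' @rdname QuantMatrix-accessors
setMethod("missingMask", "QuantMatrix",
          function(x) is.na(assay(x, "intensity")))

#' @rdname QuantMatrix-accessors
setMethod("featureLevel", "QuantMatrix",
          function(x) metadata(x)$featureLevel)

#' @rdname QuantMatrix-accessors
setMethod("intensityScale", "QuantMatrix",
          function(x) metadata(x)$intensityScale)

#' @rdname QuantMatrix-accessors
setMethod("sampleRoles", "QuantMatrix", function(x) {
  cd <- colData(x)
  if ("role" %in% names(cd)) stats::setNames(as.character(cd$role),
                                             rownames(cd)) else NULL
})

setMethod("show", "QuantMatrix", function(object) {
  x <- assay(object, "intensity")
  cat(sprintf("QuantMatrix: %d %ss x %d samples (%s scale)\n",
              nrow(x), featureLevel(object), ncol(x),
              intensityScale(object)))
  obs <- sum(!is.na(x))
  cat(sprintf("  observed cells: %d/%d (%.1f%%)\n", obs, length(x),
              100 * obs / max(1L, length(x))))
  r <- sampleRoles(object)
  if (!is.null(r)) {
    tb <- table(r)
    cat("  roles:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(object)
})

#' Accessors for PlexDesign
#'
#' `designTable()` returns the full channel table (batch, channel, role,
#' bridge_pg).
#'
#' @param x a [PlexDesign-class]
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname designTable
setMethod("designTable", "PlexDesign", function(x) x@channels)

setMethod("show", "PlexDesign", function(object) {
  ch <- object@channels
  cat(sprintf("PlexDesign: %d batches x %d channels\n",
              length(unique(ch$batch)),
              nrow(ch) / max(1L, length(unique(ch$batch)))))
  print(table(ch$role))
  invisible(object)
})

#' Accessors for PredictionScores
#'
#' `scoreMatrix()` gives the cells x types matrix, `maxScores()` the per-cell
#' maximum, `predictedType()` the argmax type, `scoreCutoff()` the
#' mean-minus-1-SD cutoff and `highConfidence()` the logical flag
#' `maxScores(x) >= scoreCutoff(x)`.
#'
#' @param x a [PredictionScores-class]
#' @name PredictionScores-accessors
#' @aliases scoreMatrix maxScores predictedType scoreCutoff highConfidence
NULL

#' @rdname PredictionScores-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname PredictionScores-accessors
#' @export
setGeneric("maxScores", function(x) standardGeneric("maxScores"))

#' @rdname PredictionScores-accessors
#' @export
setGeneric("predictedType", function(x) standardGeneric("predictedType"))

#' @rdname PredictionScores-accessors
#' @export
setGeneric("scoreCutoff", function(x) standardGeneric("scoreCutoff"))

#' @rdname PredictionScores-accessors
#' @export
setGeneric("highConfidence", function(x) standardGeneric("highConfidence"))

#' @rdname PredictionScores-accessors
setMethod("scoreMatrix", "PredictionScores", function(x) x@scores)

#' @rdname PredictionScores-accessors
setMethod("maxScores", "PredictionScores", function(x) {
  stats::setNames(apply(x@scores, 1L, max), rownames(x@scores))
})

#' @rdname PredictionScores-accessors
setMethod("predictedType", "PredictionScores", function(x) {
  ty <- colnames(x@scores)[apply(x@scores, 1L, which.max)]
  stats::setNames(ty, rownames(x@scores))
})

#' @rdname PredictionScores-accessors
setMethod("scoreCutoff", "PredictionScores", function(x) x@cutoff)

#' @rdname PredictionScores-accessors
setMethod("highConfidence", "PredictionScores", function(x) {
  m <- maxScores(x)
  stats::setNames(m >= x@cutoff, names(m))
})

setMethod("show", "PredictionScores", function(object) {
  cat(sprintf("PredictionScores: %d cells x %d types, cutoff %.3f\n",
              nrow(object@scores), ncol(object@scores), object@cutoff))
  cat(sprintf("  high-confidence cells: %d/%d\n",
              sum(highConfidence(object)), nrow(object@scores)))
  invisible(object)
})

#' Accessors for ClusterAnnotation
#'
#' `cellClusters()` returns the per-cell cluster id, `clusterLabels()` the
#' per-cluster label (`"unknown"` when no type is enriched),
#' `cellLabels()` the propagated per-cell labels and `enrichmentTable()` the
#' per-(cluster, type) hypergeometric test table.
#'
#' @param x a [ClusterAnnotation-class]
#' @name ClusterAnnotation-accessors
#' @aliases cellClusters clusterLabels cellLabels enrichmentTable
NULL

#' @rdname ClusterAnnotation-accessors
#' @export
setGeneric("cellClusters", function(x) standardGeneric("cellClusters"))

#' @rdname ClusterAnnotation-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterAnnotation-accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname ClusterAnnotation-accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname ClusterAnnotation-accessors
setMethod("cellClusters", "ClusterAnnotation", function(x) x@clusters)

#' @rdname ClusterAnnotation-accessors
setMethod("clusterLabels", "ClusterAnnotation", function(x) x@clusterLabels)

#' @rdname ClusterAnnotation-accessors
setMethod("cellLabels", "ClusterAnnotation", function(x) x@cellLabels)

#' @rdname ClusterAnnotation-accessors
setMethod("enrichmentTable", "ClusterAnnotation", function(x) x@enrichment)

setMethod("show", "ClusterAnnotation", function(object) {
  cat(sprintf("ClusterAnnotation: %d cells in %d clusters\n",
              length(object@clusters),
              length(unique(object@clusters))))
  tb <- table(object@cellLabels)
  cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  invisible(object)
})
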