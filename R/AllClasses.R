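#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData rowData<-
NULL

#' Reporter-ion intensity matrix with explicit missingness
#'
#' `QuantMatrix` is the central data container of the package: a
#' features-by-samples matrix of reporter-ion intensities built on
#' [SummarizedExperiment::SummarizedExperiment]. Missing quantifications are
#' stored as `NA` (never as zero unless a zero was genuinely observed), the
#' feature level (`"peptide"` or `"protein"`) and the intensity scale
#' (`"linear"` or `"log2"`) are carried as metadata, and per-sample
#' annotation (batch, channel, role) lives in `colData`.
#'
#' Validity requires a single assay named `"intensity"`, unique feature and
#' sample names, no negative values on the linear scale, and recognised
#' level/scale tags.
#'
#' @seealso [QuantMatrix()], [readQuantTable()], [intensities()],
#'   [missingMask()]
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

setValidity("QuantMatrix", function(object) {
  msg <- character()
  if (!("intensity" %in% names(assays(object))))
    msg <- c(msg, "assay 'intensity' is required")
  lev <- metadata(object)$featureLevel
  if (is.null(lev) || !lev %in% c("peptide", "protein"))
    msg <- c(msg, "metadata 'featureLevel' must be 'peptide' or 'protein'")
  sc <- metadata(object)$intensityScale
  if (is.null(sc) || !sc %in% c("linear", "log2"))
    msg <- c(msg, "metadata 'intensityScale' must be 'linear' or 'log2'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if ("intensity" %in% names(assays(object)) &&
      identical(sc, "linear")) {
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
      msg <- c(msg, "negative intensities are not allowed on the linear scale")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QuantMatrix
#'
#' @param intensity numeric matrix, features in rows, samples in columns.
#'   `NA` marks a missing quantification.
#' @param level feature level, `"peptide"` or `"protein"`.
#' @param scale intensity scale, `"linear"` or `"log2"`.
#' @param sampleMeta optional `data.frame` of per-sample metadata with a
#'   `sample_id` column matching `colnames(intensity)`; typical columns are
#'   `batch`, `channel` and `role` (one of `"bridge"`, `"blank"`,
#'   `"single_cell"`).
#' @param rowData optional per-feature annotation (`data.frame` or
#'   `DataFrame`), e.g. a `protein` column mapping peptides to proteins.
#'
#' @return A validated [QuantMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' qm <- QuantMatrix(m, level = "protein")
#' completeness(qm)
#' @export
QuantMatrix <- function(intensity, level = c("protein", "peptide"),
                        scale = c("linear", "log2"),
                        sampleMeta = NULL, rowData = NULL) {
  level <- match.arg(level)
  scale <- match.arg(scale)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  cd <- if (is.null(sampleMeta)) {
    DataFrame(sample_id = colnames(intensity), row.names = colnames(intensity))
  } else {
    sampleMeta <- as.data.frame(sampleMeta)
    if (!"sample_id" %in% names(sampleMeta))
      stop("sampleMeta must contain a 'sample_id' column")
    idx <- match(colnames(intensity), sampleMeta$sample_id)
    if (anyNA(idx))
      stop("sampleMeta is missing samples: ",
           paste(colnames(intensity)[is.na(idx)], collapse = ", "))
    DataFrame(sampleMeta[idx, , drop = FALSE],
              row.names = colnames(intensity))
  }
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = cd)
  if (!is.null(rowData)) rowData(se) <- DataFrame(rowData)
  metadata(se)$featureLevel <- level
  metadata(se)$intensityScale <- scale
  new("QuantMatrix", se)
}

#' Multiplex (plex) design: channels, roles and bridge inputs
#'
#' Describes the channel layout of one or more multiplexed batches: channel
#' names in plex order, the role of each channel (`bridge`, `blank` or
#' `single_cell`) and, for bridge channels, the known peptide input in
#' picograms that anchors per-cell input back-calculation.
#'
#' @seealso [plexDesign()], [validateDesign()], [estimateInput()]
#' @export
setClass("PlexDesign", representation(channels = "data.frame"))

setValidity("PlexDesign", function(object) {
  ch <- object@channels
  msg <- character()
  need <- c("batch", "channel", "role")
  if (!all(need %in% names(ch)))
    return(paste("channels table must have columns",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(ch[, c("batch", "channel")]))
    msg <- c(msg, "(batch, channel) pairs must be unique")
  if (!all(ch$role %in% c("bridge", "blank", "single_cell")))
    msg <- c(msg, "roles must be bridge, blank or single_cell")
  if ("bridge_pg" %in% names(ch)) {
    bp <- ch$bridge_pg[ch$role == "bridge"]
    if (any(is.na(bp)) || any(bp <= 0))
      msg <- c(msg, "bridge channels require bridge_pg > 0")
  } else if (any(ch$role == "bridge")) {
    msg <- c(msg, "bridge channels present but no bridge_pg column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlexDesign
#'
#' @param batch batch identifier(s), recycled against `channel`.
#' @param channel channel names in plex order (e.g. `"126"`, `"127N"`, ...).
#' @param role per-channel role: `"bridge"`, `"blank"` or `"single_cell"`.
#' @param bridge_pg peptide input (pg) for bridge channels; `NA` elsewhere.
#' @param reporter_mass optional nominal reporter mass per channel.
#' @return A [PlexDesign-class] object.
#' @export
plexDesign <- function(batch, channel, role, bridge_pg = NA_real_,
                       reporter_mass = NULL) {
  ch <- data.frame(batch = as.character(batch),
                   channel = as.character(channel),
                   role = as.character(role),
                   bridge_pg = as.numeric(bridge_pg))
  if (!is.null(reporter_mass)) ch$reporter_mass <- as.numeric(reporter_mass)
  new("PlexDesign", channels = ch)
}

#' Per-cell prediction scores from reference label transfer
#'
#' Rows are query cells, columns are reference cell types; each row is a
#' probability vector (sums to 1). The confidence cutoff is defined as the
#' mean of the per-cell maximum scores minus one (sample) standard
#' deviation; cells at or above it are "high confidence" and are the only
#' cells used by the hypergeometric cluster enrichment.
#'
#' @seealso [transferLabels()], [maxScores()], [predictedType()],
#'   [highConfidence()], [scoreCutoff()]
#' @export
setClass("PredictionScores",
         representation(scores = "matrix", cutoff = "numeric"))

setValidity("PredictionScores", function(object) {
  s <- object@scores
  msg <- character()
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "score matrix needs cell and type names")
  if (any(s < -1e-12 | s > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "scores must lie in [0, 1]")
  rs <- rowSums(s)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "score rows must sum to 1 (within 1e-9)")
  if (length(object@cutoff) != 1L)
    msg <- c(msg, "cutoff must be a single number")
  if (length(msg)) msg else TRUE
})

#' Cluster assignment with enrichment-based labels
#'
#' Holds the proteome-driven clustering of cells, the per-(cluster, type)
#' hypergeometric enrichment table computed on high-confidence cells, the
#' winning label per cluster (or `"unknown"`), and the labels propagated to
#' every cell of each cluster.
#'
#' @seealso [clusterEnrichment()], [cellLabels()], [clusterLabels()]
#' @export
setClass("ClusterAnnotation",
         representation(clusters = "integer", enrichment = "data.frame",
                        clusterLabels = "character",
                        cellLabels = "character"))

setValidity("ClusterAnnotation", function(object) {
  msg <- character()
  if (is.null(names(object@clusters)))
    msg <- c(msg, "clusters must be named by cell id")
  if (length(object@cellLabels) != length(object@clusters))
    msg <- c(msg, "one label per cell required")
  k <- sort(unique(object@clusters))
  if (length(k) && !identical(k, seq_along(k)))
    msg <- c(msg, "cluster ids must be dense integers starting at 1")
  if (length(msg)) msg else TRUE
})
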