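#' Select highly variable features
#'
#' Ranks features by variance over their observed log2 values and returns
#' the top `n`, with a deterministic lexicographic tie-break on the feature
#' id. Features with fewer than two observations are never selected.
#'
#' @param qm a log2-scale [QuantMatrix-class]
#' @param n number of features to return (must not exceed the feature
#'   count).
#' @return character vector of feature ids, variance-sorted.
#' @export
selectHVF <- function(qm, n = 600L) {
  if (n <= 0) stop("n must be positive")
  x <- intensities(qm)
  if (n > nrow(x)) stop("n exceeds the number of features")
  v <- rowVarsNA(x)
  v[is.na(v)] <- -Inf
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Overlap between proteome and reference feature ids
#'
#' Intersects two feature-id sets after case normalization (gene symbols and
#' protein ids from different sources differ in case more often than in
#' content).
#'
#' @param hvp,hvg character vectors of feature ids (e.g. highly variable
#'   proteins and genes).
#' @return list with `shared` (ids in `hvp` order, original `hvp` spelling)
#'   and `count`.
#' @export
featureOverlap <- function(hvp, hvg) {
  keep <- toupper(hvp) %in% toupper(hvg)
  shared <- hvp[keep]
  list(shared = shared, count = length(shared))
}

#' Reference label transfer with per-cell prediction scores
#'
#' Projects query cells into the reference PCA space restricted to shared
#' features and scores each cell by distance-weighted k-nearest-neighbor
#' voting over reference types: both matrices are z-scaled per feature, the
#' PCA basis is fit on the reference, each query cell's `k` nearest
#' reference cells vote with Gaussian-kernel weights (bandwidth = distance
#' to the k-th neighbor), and the per-type weight shares form a probability
#' vector. The confidence cutoff is the mean of the per-cell maximum scores
#' minus one sample standard deviation.
#'
#' @param query a complete (imputed) log2 [QuantMatrix-class] or matrix
#'   (features x cells).
#' @param reference a `ReferenceExpression` (see [generateReference()]) or a
#'   genes x cells matrix.
#' @param refLabels reference cell labels (required when `reference` is a
#'   matrix).
#' @param shared character vector of shared feature ids; defaults to the
#'   case-normalized intersection of the row names.
#' @param k neighbors (must not exceed the reference size).
#' @param nPcs principal components (capped at the shared-feature count).
#' @return a [PredictionScores-class].
#' @export
transferLabels <- function(query, reference, refLabels = NULL,
                           shared = NULL, k = 20L, nPcs = 30L) {
  qx <- if (is(query, "QuantMatrix")) intensities(query) else as.matrix(query)
  if (anyNA(qx))
    stop("query must be complete for projection; impute first")
  if (inherits(reference, "ReferenceExpression")) {
    refLabels <- reference$labels
    rx <- reference$expr
  } else {
    rx <- as.matrix(reference)
  }
  if (is.null(refLabels)) stop("reference labels are required")
  if (k > ncol(rx)) stop("k exceeds the reference size")
  if (is.null(shared))
    shared <- featureOverlap(rownames(qx), rownames(rx))$shared
  if (!length(shared))
    stop("no shared features between query and reference")
  ridx <- match(toupper(shared), toupper(rownames(rx)))
  qs <- qx[shared, , drop = FALSE]
  rs <- rx[ridx, , drop = FALSE]

  zscale <- function(m) {
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    (m - mu) / sd
  }
  qs <- zscale(qs); rs <- zscale(rs)
  nPcs <- min(nPcs, nrow(rs) - 1L, ncol(rs) - 1L)
  if (nPcs < 1L) stop("not enough shared features for a PCA basis")
  pc <- stats::prcomp(t(rs), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(nPcs), drop = FALSE]
  refEmb <- pc$x[, seq_len(nPcs), drop = FALSE]
  qryEmb <- sweep(t(qs), 2L, pc$center) %*% rot

  types <- sort(unique(refLabels))
  scores <- matrix(0, ncol(qs), length(types),
                   dimnames = list(colnames(qs), types))
  r2 <- rowSums(refEmb^2)
  for (i in seq_len(nrow(qryEmb))) {
    d2 <- r2 - 2 * drop(refEmb %*% qryEmb[i, ]) + sum(qryEmb[i, ]^2)
    d2[d2 < 0] <- 0
    nn <- order(d2)[seq_len(k)]
    h2 <- d2[nn[k]]
    wt <- if (h2 <= 0) rep(1, k) else exp(-0.5 * d2[nn] / h2)
    for (ti in seq_along(types))
      scores[i, ti] <- sum(wt[refLabels[nn] == types[ti]])
    scores[i, ] <- scores[i, ] / sum(wt)
  }
  predictionScores(scores)
}

#' Build a PredictionScores object from a score matrix
#'
#' Normalizes rounding so each row sums to exactly 1 and computes the
#' mean-minus-1-SD cutoff on the per-cell maximum scores (sample SD, n-1
#' denominator; 0 when there is a single cell).
#'
#' @param scores cells x types matrix of nonnegative scores; rows are
#'   normalized to sum to 1.
#' @return a [PredictionScores-class]
#' @export
predictionScores <- function(scores) {
  scores <- as.matrix(scores)
  rs <- rowSums(scores)
  if (any(rs <= 0)) stop("each cell needs a positive score total")
  scores <- scores / rs
  m <- apply(scores, 1L, max)
  s <- if (length(m) > 1L) stats::sd(m) else 0
  new("PredictionScores", scores = scores, cutoff = mean(m) - s)
}
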