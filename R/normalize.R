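#' Median normalization of log2 intensities
#'
#' Shifts each sample column so its observed median equals the global median
#' of the pre-normalization column medians. Missing cells are untouched; the
#' operation is idempotent.
#'
#' @param qm a log2-scale [QuantMatrix-class]
#' @return normalized [QuantMatrix-class]
#' @export
medianNormalize <- function(qm) {
  if (intensityScale(qm) != "log2")
    stop("medianNormalize expects log2 intensities (see toLog2)")
  x <- intensities(qm)
  nObs <- colSums(!is.na(x))
  if (any(nObs < 1L))
    stop("sample(s) without observations: ",
         paste(colnames(x)[nObs < 1L], collapse = ", "))
  med <- colMediansNA(x)
  target <- stats::median(med)
  x <- sweep(x, 2L, med - target, `-`)
  setAssay(qm, x)
}

#' Empirical-Bayes location/scale batch correction
#'
#' Parametric empirical-Bayes adjustment of per-batch additive (gamma) and
#' multiplicative (delta) effects on the log2 scale, following the standard
#' two-moment model: per-feature standardization, per-batch effect
#' estimation, shrinkage of the location effects toward a normal prior and
#' of the squared scale effects toward an inverse-gamma prior (both with
#' method-of-moments hyperparameters), adjustment and back-transformation.
#' Unlike complete-data implementations, every step uses observed values
#' only: missing cells remain missing.
#'
#' Features observed in fewer than two batches are passed through unadjusted
#' and flagged in the returned model; a batch with a single sample is an
#' error unless `allowSingle = TRUE`, in which case it is left unadjusted.
#'
#' @param qm a log2-scale [QuantMatrix-class]
#' @param batch per-sample batch factor; defaults to the `batch` column of
#'   `colData(qm)`.
#' @param allowSingle pass single-sample batches through instead of erroring.
#' @param maxIter,tol convergence control of the joint posterior solution
#'   for gamma*/delta*.
#' @return list with `qm` (adjusted matrix) and `model` (a `BatchModel`
#'   list: `gamma.hat`, `delta2.hat`, `gamma.star`, `delta2.star`,
#'   `gamma.bar`, `tau2`, `a.prior`, `b.prior`, `stand.mean`, `stand.sd`,
#'   `skipped` features, `batches`).
#' @export
combatAdjust <- function(qm, batch = NULL, allowSingle = FALSE,
                         maxIter = 200L, tol = 1e-8) {
  if (intensityScale(qm) != "log2")
    stop("combatAdjust expects log2 intensities")
  x <- intensities(qm)
  if (is.null(batch)) {
    cd <- colData(qm)
    if (!"batch" %in% names(cd))
      stop("no batch factor: supply `batch` or a colData 'batch' column")
    batch <- as.character(cd$batch)
  }
  batch <- as.character(batch)
  if (length(batch) != ncol(x)) stop("one batch per sample required")
  bl <- sort(unique(batch))
  nPerBatch <- table(factor(batch, levels = bl))
  single <- names(nPerBatch)[nPerBatch < 2L]
  if (length(single) && !allowSingle)
    stop("batch(es) with a single sample: ",
         paste(single, collapse = ", "),
         " (set allowSingle = TRUE to pass them through)")
  adjBatches <- setdiff(bl, single)
  if (length(single))
    warning("single-sample batch(es) passed through unadjusted: ",
            paste(single, collapse = ", "))
  if (length(adjBatches) < 2L) {
    # nothing to correct
    model <- list(batches = adjBatches, skipped = rownames(x))
    return(list(qm = qm, model = model))
  }

  G <- nrow(x)
  B <- length(adjBatches)
  obs <- !is.na(x)
  batchCols <- lapply(adjBatches, function(b) which(batch == b))
  names(batchCols) <- adjBatches

  # per-feature, per-batch observation counts and means
  nGB <- sapply(batchCols, function(j) rowSums(obs[, j, drop = FALSE]))
  mGB <- sapply(batchCols, function(j)
    rowMeans(x[, j, drop = FALSE], na.rm = TRUE))
  nGB <- matrix(nGB, G, B, dimnames = list(rownames(x), adjBatches))
  mGB <- matrix(mGB, G, B, dimnames = list(rownames(x), adjBatches))
  batchesSeen <- rowSums(nGB > 0L)
  adjust <- batchesSeen >= 2L
  skipped <- rownames(x)[!adjust]

  # weighted grand mean and pooled residual variance over observed values
  w <- nGB / pmax(1, rowSums(nGB))
  grand <- rowSums(w * ifelse(nGB > 0, mGB, 0))
  colBatchIdx <- match(batch, adjBatches)        # NA for excluded batches
  mExpand <- matrix(NA_real_, G, ncol(x))
  selCols <- !is.na(colBatchIdx)
  mExpand[, selCols] <- mGB[, colBatchIdx[selCols], drop = FALSE]
  resid <- x - mExpand
  totObs <- rowSums(nGB)
  pooledVar <- rowSums(resid^2, na.rm = TRUE) / pmax(1, totObs)
  pooledVar[pooledVar <= 0] <- NA          # constant features: skip
  adjust <- adjust & !is.na(pooledVar)
  skipped <- rownames(x)[!adjust]
  sdG <- sqrt(pooledVar)

  z <- (x - grand) / sdG

  gammaHat <- matrix(NA_real_, G, B, dimnames = dimnames(nGB))
  delta2Hat <- matrix(NA_real_, G, B, dimnames = dimnames(nGB))
  for (bi in seq_len(B)) {
    zb <- z[, batchCols[[bi]], drop = FALSE]
    gammaHat[, bi] <- rowMeans(zb, na.rm = TRUE)
    v <- apply(zb, 1L, stats::var, na.rm = TRUE)
    v[nGB[, bi] < 2L] <- 1            # no scale information
    delta2Hat[, bi] <- v
  }

  gammaBar <- tau2 <- aPrior <- bPrior <- numeric(B)
  gammaStar <- gammaHat
  delta2Star <- delta2Hat
  for (bi in seq_len(B)) {
    use <- adjust & nGB[, bi] > 0L
    g <- gammaHat[use, bi]
    d <- delta2Hat[use, bi]
    gammaBar[bi] <- mean(g)
    tau2[bi] <- stats::var(g)
    m <- mean(d); s2 <- stats::var(d)
    if (!is.finite(s2) || s2 < 1e-12) {
      aPrior[bi] <- NA; bPrior[bi] <- NA
    } else {
      aPrior[bi] <- (2 * s2 + m^2) / s2
      bPrior[bi] <- (m * s2 + m^3) / s2
    }
    idx <- which(use)
    for (g_i in idx) {
      n <- nGB[g_i, bi]
      zg <- z[g_i, batchCols[[bi]]]
      zg <- zg[!is.na(zg)]
      gh <- gammaHat[g_i, bi]
      gs <- gh; ds <- delta2Hat[g_i, bi]
      if (is.na(aPrior[bi])) {
        # degenerate scale prior (all delta2 equal): posterior is the mean
        ds <- m
        gs <- postMean(gh, gammaBar[bi], n, ds, tau2[bi])
      } else {
        for (it in seq_len(maxIter)) {
          gsNew <- postMean(gh, gammaBar[bi], n, ds, tau2[bi])
          ssq <- sum((zg - gsNew)^2)
          dsNew <- (bPrior[bi] + 0.5 * ssq) / (n / 2 + aPrior[bi] - 1)
          if (abs(gsNew - gs) < tol && abs(dsNew - ds) < tol) {
            gs <- gsNew; ds <- dsNew; break
          }
          gs <- gsNew; ds <- dsNew
        }
      }
      gammaStar[g_i, bi] <- gs
      delta2Star[g_i, bi] <- ds
    }
  }

  zAdj <- z
  for (bi in seq_len(B)) {
    j <- batchCols[[bi]]
    idx <- which(adjust & nGB[, bi] > 0L)
    zAdj[idx, j] <- (z[idx, j, drop = FALSE] - gammaStar[idx, bi]) /
      sqrt(delta2Star[idx, bi])
  }
  xAdj <- zAdj * sdG + grand
  xAdj[!adjust, ] <- x[!adjust, ]
  xAdj[, !batch %in% adjBatches] <- x[, !batch %in% adjBatches, drop = FALSE]
  xAdj[is.na(x)] <- NA

  model <- list(batches = adjBatches, gamma.hat = gammaHat,
                delta2.hat = delta2Hat, gamma.star = gammaStar,
                delta2.star = delta2Star, gamma.bar = gammaBar,
                tau2 = tau2, a.prior = aPrior, b.prior = bPrior,
                stand.mean = grand, stand.sd = sdG, skipped = skipped)
  list(qm = setAssay(qm, xAdj), model = model)
}

postMean <- function(gHat, gBar, n, d2, t2) {
  if (!is.finite(t2) || t2 <= 0) return(gBar)
  (t2 * n * gHat + d2 * gBar) / (t2 * n + d2)
}

#' Impute missing values for analyses requiring complete data
#'
#' Features observed in fewer than `minObsRate` of the samples are dropped
#' first; the remaining missing cells are filled either by the average of
#' the `k` nearest samples (Euclidean distance on co-observed log2 values;
#' only neighbors observing the feature contribute) or by low-value draws
#' around a per-sample low quantile (a "MinProb"-style alternative for
#' missingness dominated by detection limits). Observed values are never
#' altered; imputed positions are flagged in `metadata(qm)$imputedMask`.
#'
#' @param qm a log2-scale [QuantMatrix-class]
#' @param method `"knn"` (default, deterministic) or `"minprob"`.
#' @param k neighbors for `"knn"`.
#' @param minObsRate observation-rate floor below which a feature is
#'   dropped (fraction of samples).
#' @param seed seed for `"minprob"` draws.
#' @return complete [QuantMatrix-class] with `metadata()$imputedMask`.
#' @export
imputeMissing <- function(qm, method = c("knn", "minprob"), k = 5L,
                          minObsRate = 0.3, seed = 1L) {
  method <- match.arg(method)
  if (intensityScale(qm) != "log2")
    stop("impute on the log2 scale")
  x <- intensities(qm)
  obsRate <- rowMeans(!is.na(x))
  keep <- obsRate >= minObsRate
  if (!any(keep)) stop("no feature passes the observation-rate floor")
  qm <- qm[keep, ]
  x <- intensities(qm)
  if (any(rowSums(!is.na(x)) == 0L))
    stop("feature(s) with zero observations reached the imputer")
  mask <- is.na(x)
  if (!any(mask)) {
    metadata(qm)$imputedMask <- mask
    return(qm)
  }
  if (method == "knn") {
    n <- ncol(x)
    d2 <- matrix(Inf, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      shared <- !is.na(x[, i]) & !is.na(x[, j])
      if (any(shared)) {
        d2[i, j] <- d2[j, i] <- mean((x[shared, i] - x[shared, j])^2)
      }
    }
    diag(d2) <- Inf
    for (j in seq_len(n)) {
      miss <- which(mask[, j])
      if (!length(miss)) next
      ord <- order(d2[, j])
      for (g in miss) {
        donors <- ord[!is.na(x[g, ord])]
        donors <- donors[seq_len(min(k, length(donors)))]
        x[g, j] <- mean(x[g, donors])
      }
    }
  } else {
    set.seed(seed)
    for (j in seq_len(ncol(x))) {
      miss <- which(mask[, j])
      if (!length(miss)) next
      objs <- x[!mask[, j], j]
      lo <- stats::quantile(objs, 0.01, names = FALSE)
      s <- stats::sd(objs) * 0.3
      x[miss, j] <- stats::rnorm(length(miss), lo, s)
    }
  }
  out <- setAssay(qm, x)
  metadata(out)$imputedMask <- mask
  out
}
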