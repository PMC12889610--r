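#' One-vs-rest group statistics per protein
#'
#' For every cell type and protein, computes the mean log2 difference
#' between cells of that type and all other labeled cells, the pooled
#' residual variance and its degrees of freedom, using observed values only
#' (missing quantifications are simply absent, never imputed here).
#' Proteins with fewer than `minObs` observations in either group for a
#' contrast are skipped and recorded.
#'
#' @param qm normalized, batch-corrected, non-imputed log2
#'   [QuantMatrix-class].
#' @param labels named character vector of per-cell labels (cells absent
#'   from `colnames(qm)` are ignored; label `"unknown"` is excluded from
#'   contrasts but its cells still count toward "rest" — set
#'   `dropUnknown = TRUE` to exclude them entirely).
#' @param minObs minimum observations per group.
#' @param dropUnknown exclude `"unknown"` cells from the rest group.
#' @return `data.frame` with columns `protein`, `contrast`, `n1`, `n2`,
#'   `logFC`, `s2`, `df`; skipped (protein, contrast) pairs in
#'   `attr(, "skipped")`.
#' @export
fitOneVsRest <- function(qm, labels, minObs = 10L, dropUnknown = TRUE) {
  x <- intensities(qm)
  labels <- labels[intersect(names(labels), colnames(x))]
  if (dropUnknown) labels <- labels[labels != "unknown"]
  if (length(unique(labels)) < 2L)
    stop("need >= 2 labels for one-vs-rest contrasts")
  x <- x[, names(labels), drop = FALSE]
  types <- sort(unique(labels))
  res <- NULL; skipped <- NULL
  for (ty in types) {
    g1 <- x[, labels == ty, drop = FALSE]
    g2 <- x[, labels != ty, drop = FALSE]
    n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
    ok <- n1 >= minObs & n2 >= minObs
    m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
    ss1 <- rowSums((g1 - m1)^2, na.rm = TRUE)
    ss2 <- rowSums((g2 - m2)^2, na.rm = TRUE)
    df <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / df
    if (any(ok))
      res <- rbind(res, data.frame(
        protein = rownames(x)[ok], contrast = ty, n1 = n1[ok],
        n2 = n2[ok], logFC = (m1 - m2)[ok], s2 = s2[ok], df = df[ok],
        stringsAsFactors = FALSE, row.names = NULL))
    if (any(!ok))
      skipped <- rbind(skipped, data.frame(
        protein = rownames(x)[!ok], contrast = ty, n1 = n1[!ok],
        n2 = n2[!ok], stringsAsFactors = FALSE, row.names = NULL))
  }
  if (is.null(res)) stop("no protein passed the per-group observation floor")
  attr(res, "skipped") <- skipped
  res
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-protein residual variances toward a common prior under a
#' scaled inverse-chi-square model. The prior degrees of freedom `d0` and
#' prior variance `s02` are estimated by method-of-moments on `log(s2)`
#' (matching the moments of log chi-square via the digamma/trigamma
#' functions), and the posterior variance is the degrees-of-freedom-weighted
#' average `s2tilde = (d0*s02 + df*s2) / (d0 + df)`. With `d0 = 0` the
#' moderated statistics reduce to ordinary two-sample t statistics; with
#' `d0 = Inf` every variance equals `s02`.
#'
#' @param s2 per-protein residual variances (> 0 entries are used for
#'   estimation; zeros are allowed and shrink fully toward the prior
#'   contribution).
#' @param df residual degrees of freedom (scalar or per-protein).
#' @param d0 optional prior df override (0, positive, or `Inf`).
#' @return list with `d0`, `s02`, `s2tilde`.
#' @export
moderateVariances <- function(s2, df, d0 = NULL) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  pos <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(pos) < 2L && is.null(d0))
    stop("need >= 2 positive variances to estimate the prior")
  if (is.null(d0)) {
    e <- log(s2[pos]) - digamma(df[pos] / 2) + log(df[pos] / 2)
    evar <- stats::var(e) - mean(trigamma(df[pos] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigammaInverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess dispersion beyond chi-square sampling noise: the common
      # variance limit, estimated by the arithmetic mean
      d0 <- Inf
      s02 <- mean(s2[pos])
    }
  } else if (is.infinite(d0)) {
    s02 <- mean(s2[pos])
  } else if (d0 == 0) {
    s02 <- NA_real_
  } else {
    e <- log(s2[pos]) - digamma(df[pos] / 2) + log(df[pos] / 2)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2tilde <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + df * s2) / (d0 + df)
  list(d0 = d0, s02 = s02, s2tilde = s2tilde)
}

# Newton inversion of the trigamma function (solves trigamma(x) = y).
trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Multiple-testing adjustment
#'
#' Bonferroni by default: `min(1, m * p)` with `m` the number of tests in
#' the family (one one-vs-rest contrast). Other methods delegate to
#' [stats::p.adjust].
#'
#' @param p raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or any [stats::p.adjust] method.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values, same order as `p`.
#' @export
adjustPvalues <- function(p, method = "bonferroni", m = length(p)) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (method == "bonferroni") pmin(1, p * m)
  else stats::p.adjust(p, method = method, n = m)
}

#' One-vs-rest moderated-t differential abundance
#'
#' Full differential-abundance pipeline: per-contrast group statistics
#' ([fitOneVsRest()]), empirical-Bayes variance moderation
#' ([moderateVariances()], one prior per contrast), moderated t statistics
#' `t = logFC / sqrt(s2tilde * (1/n1 + 1/n2))` with `d0 + df` degrees of
#' freedom, two-sided p-values, and Bonferroni adjustment within each
#' contrast (family size = proteins tested in that contrast).
#'
#' @inheritParams fitOneVsRest
#' @param d0 optional prior-df override passed to [moderateVariances()].
#' @return `DEResult` `data.frame`: one row per protein x contrast with
#'   `n1`, `n2`, `logFC`, `s2`, `d0`, `s02`, `s2tilde`, `df`, `df_total`,
#'   `t`, `p`, `p_adj`; skipped pairs kept in `attr(, "skipped")`.
#' @export
runDifferentialAbundance <- function(qm, labels, minObs = 10L,
                                     dropUnknown = TRUE, d0 = NULL) {
  fit <- fitOneVsRest(qm, labels, minObs = minObs,
                      dropUnknown = dropUnknown)
  out <- NULL
  for (ty in unique(fit$contrast)) {
    sub <- fit[fit$contrast == ty, , drop = FALSE]
    mod <- moderateVariances(sub$s2, sub$df, d0 = d0)
    se <- sqrt(mod$s2tilde * (1 / sub$n1 + 1 / sub$n2))
    t <- sub$logFC / se
    # total df capped at the pooled residual df of the contrast, so an
    # infinite prior yields the common-variance t rather than a normal
    dfTotal <- pmin(mod$d0 + sub$df, sum(sub$df))
    p <- 2 * stats::pt(-abs(t), dfTotal)
    sub$d0 <- mod$d0
    sub$s02 <- mod$s02
    sub$s2tilde <- mod$s2tilde
    sub$df_total <- dfTotal
    sub$t <- t
    sub$p <- p
    sub$p_adj <- adjustPvalues(p, "bonferroni", m = nrow(sub))
    out <- rbind(out, sub)
  }
  attr(out, "skipped") <- attr(fit, "skipped")
  out
}
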