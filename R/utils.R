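`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed per pipeline stage: keeps stages independent while a
# single global seed reproduces everything. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 100003
  as.integer((as.numeric(seed) %% 2147480000 * 131 + h * 7919 + 17) %%
               2147483629)
}

# Multiplicative log-normal noise with mean 1 and the requested coefficient
# of variation.
lognormalNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

logmsg <- function(fmt, ...) {
  if (isTRUE(getOption("plexcell.verbose", TRUE)))
    message(sprintf("[plexcell %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  invisible(NULL)
}

# Column medians/variances over observed values only.
colMediansNA <- function(x) apply(x, 2L, stats::median, na.rm = TRUE)
rowVarsNA <- function(x) apply(x, 1L, stats::var, na.rm = TRUE)

#' Convert a QuantMatrix between linear and log2 scales
#'
#' Observed zeros become missing when log-transforming (reporter-ion
#' intensities are strictly positive in practice, a stored zero carries no
#' usable quantitative information on the log scale).
#'
#' @param qm a [QuantMatrix-class]
#' @return a [QuantMatrix-class] on the requested scale.
#' @export
toLog2 <- function(qm) {
  if (intensityScale(qm) == "log2") return(qm)
  x <- intensities(qm)
  x[!is.na(x) & x <= 0] <- NA
  x <- log2(x)
  out <- qm
  assay(out, "intensity", withDimnames = FALSE) <- x
  metadata(out)$intensityScale <- "log2"
  out
}

#' @rdname toLog2
#' @export
toLinear <- function(qm) {
  if (intensityScale(qm) == "linear") return(qm)
  x <- 2^intensities(qm)
  out <- qm
  assay(out, "intensity", withDimnames = FALSE) <- x
  metadata(out)$intensityScale <- "linear"
  out
}

# Replace the intensity assay, keeping everything else.
setAssay <- function(qm, x, scale = intensityScale(qm)) {
  out <- qm
  assay(out, "intensity", withDimnames = FALSE) <- x
  metadata(out)$intensityScale <- scale
  out
}

#' @importFrom SummarizedExperiment assay<-
NULL
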