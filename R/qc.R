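#' Per-channel summed intensities and identification counts
#'
#' Sums reporter-ion intensities over observed features for every sample and
#' counts identified (observed) features, the starting point for the role
#' fold-difference and per-cell input back-calculation QC.
#'
#' @param qm a linear-scale [QuantMatrix-class]; batch/channel/role columns
#'   of `colData` are carried through when present.
#' @return A `data.frame` with one row per sample: `sample_id`, any of
#'   `batch`/`channel`/`role`, `sum_intensity`, `n_features`, and
#'   `all_missing` flagging samples without a single observation.
#' @export
channelSums <- function(qm) {
  if (intensityScale(qm) != "linear")
    stop("channelSums expects a linear-scale matrix")
  x <- intensities(qm)
  out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
  cd <- as.data.frame(colData(qm))
  for (col in intersect(c("batch", "channel", "role"), names(cd)))
    out[[col]] <- cd[[col]]
  out$sum_intensity <- colSums(x, na.rm = TRUE)
  out$n_features <- colSums(!is.na(x))
  out$all_missing <- out$n_features == 0L
  rownames(out) <- NULL
  out
}

#' Fold differences between channel roles
#'
#' Ratios of median summed intensity between roles: bridge vs single cell
#' and single cell vs blank. A role absent by design yields `NA` (undefined)
#' rather than an error; a present role with zero median is an error.
#'
#' @param summary output of [channelSums()] (must contain a `role` column).
#' @return list with `bridge_vs_cell` and `cell_vs_blank`.
#' @export
foldDifferences <- function(summary) {
  if (!"role" %in% names(summary))
    stop("channel summary lacks a 'role' column")
  med <- function(role) {
    s <- summary$sum_intensity[summary$role == role]
    if (!length(s)) return(NA_real_)
    stats::median(s)
  }
  ratio <- function(a, b) {
    ma <- med(a); mb <- med(b)
    if (is.na(ma) || is.na(mb)) return(NA_real_)
    if (mb == 0) stop("zero median for role ", b)
    ma / mb
  }
  list(bridge_vs_cell = ratio("bridge", "single_cell"),
       cell_vs_blank = ratio("single_cell", "blank"))
}

#' Back-calculate per-cell peptide input from bridge channels
#'
#' Each bridge channel carries a known peptide input (pg). Within a batch,
#' the median bridge-channel summed intensity serves as the reference for a
#' single bridge channel's input, and each single cell's input is estimated
#' as `bridge_pg * cell_sum / bridge_reference`. With two bridge channels the
#' reference is the median of their sums against the per-channel input (150
#' pg each when 300 pg is split over two channels), not the pooled total.
#'
#' @param summary output of [channelSums()] with `batch` and `role`.
#' @param design a [PlexDesign-class] providing `bridge_pg` per bridge
#'   channel.
#' @return `summary` with an `est_input_pg` column (NA for non-cell
#'   channels).
#' @export
estimateInput <- function(summary, design) {
  ch <- designTable(design)
  need <- c("batch", "channel", "role")
  if (!all(need %in% names(summary)))
    stop("channel summary needs batch/channel/role columns")
  summary$est_input_pg <- NA_real_
  for (b in unique(summary$batch)) {
    rows <- summary$batch == b
    bridgeRows <- rows & summary$role == "bridge"
    if (!any(bridgeRows))
      stop("batch ", b, " has no bridge channel; cannot estimate input")
    bpg <- ch$bridge_pg[ch$batch == b & ch$role == "bridge"]
    bpg <- bpg[!is.na(bpg)]
    if (!length(bpg)) stop("batch ", b, " has no known bridge_pg")
    bridgePg <- stats::median(bpg)
    bridgeRef <- stats::median(summary$sum_intensity[bridgeRows])
    if (bridgeRef <= 0)
      stop("batch ", b, " has non-positive bridge reference sum")
    cellRows <- rows & summary$role == "single_cell"
    summary$est_input_pg[cellRows] <-
      bridgePg * summary$sum_intensity[cellRows] / bridgeRef
  }
  summary
}

#' Data completeness of a QuantMatrix
#'
#' Fraction of observed feature-by-sample cells among features with at least
#' one observation in the considered samples. Features entirely missing in
#' the subset do not enter the denominator, so padding the matrix with
#' never-identified features leaves completeness unchanged.
#'
#' @param qm a [QuantMatrix-class]
#' @param samples optional character vector of sample ids restricting the
#'   computation (e.g. single-cell channels only).
#' @return completeness fraction in \[0, 1\].
#' @export
completeness <- function(qm, samples = NULL) {
  x <- intensities(qm)
  if (!is.null(samples)) {
    if (!length(samples)) stop("empty sample subset")
    missing <- setdiff(samples, colnames(x))
    if (length(missing))
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    x <- x[, samples, drop = FALSE]
  }
  keep <- rowSums(!is.na(x)) > 0L
  if (!any(keep)) return(0)
  x <- x[keep, , drop = FALSE]
  sum(!is.na(x)) / length(x)
}

#' Cumulative sensitivity curve over acquisition runs
#'
#' Given per-run identified-feature sets, computes (i) the cumulative number
#' of unique features as runs are sampled one by one, averaged over random
#' orderings, (ii) the total sensitivity (union over all runs), and (iii)
#' the mean local sensitivity (average per-run set size).
#'
#' @param idSets list of character vectors, one per run.
#' @param nPerm number of random orderings to average over; `0` uses the
#'   given order only.
#' @param exact if `TRUE`, enumerate all `factorial(n)` orderings instead of
#'   sampling (small run counts only).
#' @param seed seed for the sampled orderings.
#' @return list with `cumulative` (length = number of runs), `total`,
#'   `meanLocal`, and `perRun` (set sizes).
#' @export
sensitivityCurve <- function(idSets, nPerm = 100L, exact = FALSE,
                             seed = 1L) {
  n <- length(idSets)
  if (n == 0L) stop("no runs supplied")
  idSets <- lapply(idSets, unique)
  curveFor <- function(ord) {
    seen <- character()
    out <- numeric(n)
    for (i in seq_len(n)) {
      seen <- unique(c(seen, idSets[[ord[i]]]))
      out[i] <- length(seen)
    }
    out
  }
  if (exact) {
    perms <- permuteAll(n)
    cum <- rowMeans(vapply(perms, curveFor, numeric(n)))
  } else if (nPerm <= 0L) {
    cum <- curveFor(seq_len(n))
  } else {
    set.seed(seed)
    cum <- rowMeans(vapply(seq_len(nPerm),
                           function(i) curveFor(sample.int(n)),
                           numeric(n)))
  }
  list(cumulative = cum,
       total = length(unique(unlist(idSets, use.names = FALSE))),
       meanLocal = mean(lengths(idSets)),
       perRun = lengths(idSets))
}

permuteAll <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(permuteAll(n - 1L), function(p) c(i, (seq_len(n)[-i])[p]))
  }))
}
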