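#' Read a wide feature-by-sample intensity table
#'
#' Ingests the wide TSV/CSV tables produced by isobaric quantification tools
#' (one feature-id column followed by one column per sample). Empty cells and
#' `"NA"` are treated as missing; observed zeros are kept as zeros unless
#' `zeroAsMissing = TRUE` (quantification tools conflate the two
#' inconsistently, so the choice is explicit).
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file. The
#'   first column is taken as the feature id.
#' @param level feature level of the table, `"protein"` or `"peptide"`.
#' @param zeroAsMissing if `TRUE`, observed zeros are converted to missing.
#' @param sep field separator; guessed from the file extension when `NULL`.
#' @param sampleMeta optional per-sample metadata `data.frame` passed to
#'   [QuantMatrix()].
#' @return A linear-scale [QuantMatrix-class].
#' @export
readQuantTable <- function(path, level = c("protein", "peptide"),
                           zeroAsMissing = FALSE, sep = NULL,
                           sampleMeta = NULL) {
  level <- match.arg(level)
  sep <- sep %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
                   else "\t")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("quant table needs one feature-id column and >=1 sample columns")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature id(s): ", paste(dup, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  # columns that are entirely missing are read as logical NA
  allNA <- vapply(vals, function(v) is.logical(v) && all(is.na(v)),
                  logical(1L))
  vals[allNA] <- lapply(vals[allNA], as.numeric)
  nonnum <- !vapply(vals, is.numeric, logical(1L))
  if (any(nonnum))
    stop("non-numeric sample column(s): ",
         paste(names(vals)[nonnum], collapse = ", "))
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (zeroAsMissing) x[!is.na(x) & x == 0] <- NA
  QuantMatrix(x, level = level, scale = "linear", sampleMeta = sampleMeta)
}

#' Write a QuantMatrix as a wide table
#'
#' Inverse of [readQuantTable()]: missing values are written as `NA`. The
#' separator follows the file extension (`.csv` comma, otherwise tab).
#'
#' @param qm a [QuantMatrix-class]
#' @param path output path.
#' @param idColumn name for the feature-id column.
#' @return `path`, invisibly.
#' @export
writeQuantTable <- function(qm, path, idColumn = "feature_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- intensities(qm)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write per-sample metadata
#'
#' The metadata table has one row per sample with columns `sample_id`,
#' `batch`, `channel`, `role` (`bridge`, `blank` or `single_cell`) and
#' optionally `bridge_pg` plus further covariates (chip, LC column).
#'
#' @param path TSV path.
#' @return `readSampleMeta`: a validated `data.frame`.
#' @export
readSampleMeta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "batch", "channel", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  if (anyDuplicated(df[, c("batch", "channel")]))
    stop("(batch, channel) must be unique in metadata")
  bad <- setdiff(unique(df$role), c("bridge", "blank", "single_cell"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname readSampleMeta
#' @param meta a sample metadata `data.frame`.
#' @export
writeSampleMeta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a plex design as JSON
#'
#' The JSON layout is a list of batches, each with `batch`, `channels`
#' (ordered names), `roles` and optional `bridge_pg` (one value per bridge
#' channel position, `null` elsewhere).
#'
#' @param path JSON path.
#' @return `readPlexDesign`: a [PlexDesign-class].
#' @export
readPlexDesign <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(js)) js <- split(js, seq_len(nrow(js)))
  tab <- do.call(rbind, lapply(js, function(b) {
    data.frame(batch = as.character(b$batch),
               channel = as.character(unlist(b$channels)),
               role = as.character(unlist(b$roles)),
               bridge_pg = if (is.null(b$bridge_pg)) NA_real_ else
                 as.numeric(unlist(b$bridge_pg)),
               stringsAsFactors = FALSE)
  }))
  new("PlexDesign", channels = tab)
}

#' @rdname readPlexDesign
#' @param design a [PlexDesign-class].
#' @export
writePlexDesign <- function(design, path) {
  ch <- designTable(design)
  out <- lapply(split(ch, ch$batch), function(b) {
    list(batch = b$batch[1L], channels = b$channel, roles = b$role,
         bridge_pg = b$bridge_pg)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Validate a design / metadata / matrix bundle
#'
#' Checks that every sample in the metadata (and, when given, every column of
#' the matrix) maps to exactly one (batch, channel, role) of the design, and
#' reports per-role counts. When input estimation is requested, every batch
#' must carry at least one bridge channel with a known input.
#'
#' @param design a [PlexDesign-class]
#' @param meta sample metadata `data.frame` (see [readSampleMeta()]).
#' @param qm optional [QuantMatrix-class] whose columns must match
#'   `meta$sample_id`.
#' @param requireBridge error when a batch has no bridge channel (set this
#'   when per-cell input estimation is planned).
#' @return A list with `meta` (metadata joined with design `bridge_pg`),
#'   `roleCounts` (overall table) and `batchRoleCounts`.
#' @export
validateDesign <- function(design, meta, qm = NULL, requireBridge = FALSE) {
  ch <- designTable(design)
  key <- function(b, c) paste(b, c, sep = "\r")
  idx <- match(key(meta$batch, meta$channel), key(ch$batch, ch$channel))
  if (anyNA(idx))
    stop("sample(s) with unknown (batch, channel): ",
         paste(meta$sample_id[is.na(idx)], collapse = ", "))
  if (!all(meta$role == ch$role[idx]))
    stop("role mismatch between metadata and design for: ",
         paste(meta$sample_id[meta$role != ch$role[idx]], collapse = ", "))
  meta$bridge_pg <- ch$bridge_pg[idx]
  if (!is.null(qm)) {
    unmatched <- setdiff(colnames(qm), meta$sample_id)
    if (length(unmatched))
      stop("matrix sample(s) missing from metadata: ",
           paste(unmatched, collapse = ", "))
  }
  if (requireBridge) {
    nb <- tapply(meta$role == "bridge", meta$batch, sum)
    if (any(nb == 0))
      stop("batch(es) without bridge channels: ",
           paste(names(nb)[nb == 0], collapse = ", "))
  }
  list(meta = meta,
       roleCounts = table(meta$role),
       batchRoleCounts = table(meta$batch, meta$role))
}

#' Aggregate a peptide-level QuantMatrix to proteins
#'
#' Sums observed linear peptide intensities within each protein group; a
#' protein with no observed peptide in a sample stays missing.
#'
#' @param qm a linear-scale, peptide-level [QuantMatrix-class]
#' @param proteinMap named character vector mapping peptide id to protein id;
#'   defaults to the `protein` column of `rowData(qm)`.
#' @return A protein-level linear [QuantMatrix-class].
#' @export
aggregateProteins <- function(qm, proteinMap = NULL) {
  if (featureLevel(qm) != "peptide")
    stop("aggregateProteins expects a peptide-level matrix")
  if (intensityScale(qm) != "linear")
    stop("aggregate on the linear scale")
  if (is.null(proteinMap)) {
    rd <- rowData(qm)
    if (!"protein" %in% names(rd))
      stop("no protein map: supply proteinMap or a rowData 'protein' column")
    proteinMap <- stats::setNames(as.character(rd$protein), rownames(qm))
  }
  pm <- proteinMap[rownames(qm)]
  if (anyNA(pm)) stop("proteinMap lacks some peptides")
  x <- intensities(qm)
  prot <- sort(unique(pm))
  out <- matrix(NA_real_, length(prot), ncol(x),
                dimnames = list(prot, colnames(x)))
  grp <- split(seq_len(nrow(x)), pm)
  for (p in names(grp)) {
    sub <- x[grp[[p]], , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0L] <- NA
    out[p, ] <- s
  }
  QuantMatrix(out, level = "protein", scale = "linear",
              sampleMeta = as.data.frame(colData(qm)))
}
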