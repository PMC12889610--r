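#' Configuration for the ground-truth single-cell proteome generator
#'
#' Defines the study conditions the generator emulates: a multiplexed design
#' with bridge channels carrying a known bulk peptide input, empty (blank)
#' channels, and single-cell channels with log-normally distributed peptide
#' input of a few tens of picograms; cell-type structure through disjoint
#' marker protein sets; per-batch location/scale effects on the log2 scale;
#' and a permeabilization artifact in which a fraction of cells loses part of
#' its cytosolic protein content before isolation.
#'
#' @param nBatches number of multiplexed batches (one LC-MS run each).
#' @param layout named integer vector `c(bridge=, blank=, single_cell=)`
#'   giving channels per batch; the default 2 + 3 + 27 = 32-plex layout
#'   places bridges on 126/135ND and blanks on 134C/135N/135CD.
#' @param nProteins,peptidesPerProtein proteome size; peptide counts per
#'   protein are `1 + Poisson(peptidesPerProtein - 1)`.
#' @param nCellTypes number of cell types.
#' @param typeProportions type frequencies (sum to 1). The default for six
#'   types includes one rare (2 percent) granulocyte-like population.
#' @param markerFraction fraction of proteins assigned as markers to each
#'   type (disjoint sets).
#' @param markerLog2Effect log2 abundance boost of a marker in its own type.
#' @param cellInputMedianPg,cellInputSigma median (pg) and log-scale sigma of
#'   the log-normal per-cell peptide input.
#' @param bridgePg peptide input per bridge channel (pg).
#' @param batchLocationSd,batchScaleSd SDs of the per-(feature, batch)
#'   additive log2 effect and of the log multiplicative noise-scale effect.
#' @param permFraction fraction of cells that are permeabilized.
#' @param cytosolicFraction fraction of proteins flagged cytosolic.
#' @param leakFactor multiplier lambda (nonnegative, below 1) applied to
#'   cytosolic features of permeabilized cells.
#' @param interferenceEps coefficient of summed bridge-channel signal leaking
#'   into every channel of the plex.
#' @param proteinLogSd,peptideLogSd,cellNoiseSd log2 SDs of protein baseline
#'   abundance, peptide ionization propensity, and cell-to-cell biological
#'   noise.
#' @param unitsPerPg arbitrary intensity units per pg of peptide input.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return A validated `GroundTruthConfig` (list).
#' @export
groundTruthConfig <- function(nBatches = 20L,
                              layout = c(bridge = 2L, blank = 3L,
                                         single_cell = 27L),
                              nProteins = 300L, peptidesPerProtein = 3,
                              nCellTypes = 6L,
                              typeProportions = NULL,
                              markerFraction = 0.04, markerLog2Effect = 2,
                              cellInputMedianPg = 14.2,
                              cellInputSigma = 0.35,
                              bridgePg = 150,
                              batchLocationSd = 0.6, batchScaleSd = 0.15,
                              permFraction = 0.3, cytosolicFraction = 0.6,
                              leakFactor = 0.4, interferenceEps = 1e-4,
                              proteinLogSd = 1.5, peptideLogSd = 0.5,
                              cellNoiseSd = 0.3, unitsPerPg = 1e4,
                              seed = 1L) {
  if (is.null(typeProportions)) {
    typeProportions <- if (nCellTypes == 6L)
      c(0.33, 0.22, 0.16, 0.15, 0.12, 0.02)
    else rep(1 / nCellTypes, nCellTypes)
  }
  cfg <- list(nBatches = as.integer(nBatches), layout = layout,
              nProteins = as.integer(nProteins),
              peptidesPerProtein = peptidesPerProtein,
              nCellTypes = as.integer(nCellTypes),
              typeProportions = typeProportions,
              markerFraction = markerFraction,
              markerLog2Effect = markerLog2Effect,
              cellInputMedianPg = cellInputMedianPg,
              cellInputSigma = cellInputSigma, bridgePg = bridgePg,
              batchLocationSd = batchLocationSd,
              batchScaleSd = batchScaleSd, permFraction = permFraction,
              cytosolicFraction = cytosolicFraction,
              leakFactor = leakFactor, interferenceEps = interferenceEps,
              proteinLogSd = proteinLogSd, peptideLogSd = peptideLogSd,
              cellNoiseSd = cellNoiseSd, unitsPerPg = unitsPerPg,
              seed = as.integer(seed))
  validateGroundTruthConfig(cfg)
  class(cfg) <- "GroundTruthConfig"
  cfg
}

validateGroundTruthConfig <- function(cfg) {
  fr <- c(cfg$markerFraction, cfg$permFraction, cfg$cytosolicFraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$leakFactor < 0 || cfg$leakFactor >= 1)
    stop("leakFactor must lie in [0, 1)")
  if (!all(c("bridge", "blank", "single_cell") %in% names(cfg$layout)))
    stop("layout needs named entries bridge, blank, single_cell")
  if (any(cfg$layout < 0) || cfg$layout[["single_cell"]] < 1)
    stop("layout requires >=1 single-cell channel and no negative counts")
  if (cfg$nBatches < 1 || cfg$nProteins < 1)
    stop("counts must be positive")
  if (cfg$bridgePg <= 0 || cfg$cellInputMedianPg <= 0)
    stop("pg values must be > 0")
  if (abs(sum(cfg$typeProportions) - 1) > 1e-6 ||
      length(cfg$typeProportions) != cfg$nCellTypes)
    stop("typeProportions must have one entry per type and sum to 1")
  invisible(cfg)
}

# Canonical 32-plex channel names (18 standard + 14 deuterated isotopologues)
# with the default role layout: bridges on 126/135ND, blanks on the
# isotopically non-adjacent 134C/135N/135CD, 27 single-cell channels.
tmt32Channels <- function() {
  std <- c("126", paste0(rep(127:135, each = 2), c("N", "C")))
  std <- std[std != "135C"]                      # 18 names, 126..135N
  deut <- paste0(rep(c(127:132, 135), each = 2), c("ND", "CD"))
  c(std, deut)
}

plexChannelNames <- function(layout) {
  n <- sum(layout)
  if (n == 32L && identical(unname(layout[c("bridge", "blank",
                                            "single_cell")]),
                            c(2L, 3L, 27L))) {
    ch <- tmt32Channels()
    roles <- rep("single_cell", 32L)
    names(roles) <- ch
    roles[c("126", "135ND")] <- "bridge"
    roles[c("134C", "135N", "135CD")] <- "blank"
    return(data.frame(channel = ch, role = unname(roles[ch]),
                      stringsAsFactors = FALSE))
  }
  ch <- sprintf("Ch%02d", seq_len(n))
  data.frame(channel = ch,
             role = rep(c("bridge", "blank", "single_cell"),
                        times = layout[c("bridge", "blank",
                                         "single_cell")]),
             stringsAsFactors = FALSE)
}

#' Generate a ground-truth single-cell proteome dataset
#'
#' Draws latent cell types, per-cell inputs, permeabilization flags and the
#' noise-free feature-by-channel abundance matrix implied by a
#' [groundTruthConfig()]. Bridge channels carry the population-average
#' proteome scaled to `bridgePg`; blank channels carry zero true signal.
#' Permeabilized cells have their cytosolic features multiplied by
#' `leakFactor` after scaling to the nominal input, so their realized
#' (detectable) content is lower than the nominal input.
#'
#' @param config a `GroundTruthConfig`.
#' @return A `GroundTruthDataset`: a list with elements `config`, `proteins`,
#'   `features` (peptides), `cells`, `samples`, `abundance` (linear,
#'   features x all channels), `typeMeans` (protein log2 means per type),
#'   `batchLocation` and `batchScale` (latent per-feature batch effects),
#'   and `design` (a [PlexDesign-class]).
#' @export
generateTruth <- function(config) {
  validateGroundTruthConfig(config)
  set.seed(config$seed)
  np <- config$nProteins
  types <- sprintf("T%d", seq_len(config$nCellTypes))

  proteinId <- sprintf("P%04d", seq_len(np))
  baseline <- stats::rnorm(np, mean = 6, sd = config$proteinLogSd)
  # Cytosolic flags are assigned stratified across abundance deciles so the
  # cytosolic share of total protein MASS concentrates at the configured
  # fraction. A proteome of a few hundred simulated proteins with
  # heavy-tailed abundances would otherwise let a handful of dominant
  # proteins set the effective permeabilization leak, which the real
  # (thousands-of-proteins) system does not do.
  cytosolic <- rep(FALSE, np)
  ord <- order(baseline)
  strata <- split(ord, cut(seq_along(ord), breaks = 10, labels = FALSE))
  for (str in strata) {
    pick <- sample(str, round(config$cytosolicFraction * length(str)))
    cytosolic[pick] <- TRUE
  }

  nMark <- round(config$markerFraction * np)
  markerType <- rep(NA_character_, np)
  pool <- seq_len(np)
  for (ty in types) {
    pick <- sample(pool, min(nMark, length(pool)))
    markerType[pick] <- ty
    pool <- setdiff(pool, pick)
  }
  typeMeans <- matrix(baseline, np, length(types),
                      dimnames = list(proteinId, types))
  for (ty in types)
    typeMeans[which(markerType == ty), ty] <-
      typeMeans[which(markerType == ty), ty] + config$markerLog2Effect

  nPep <- 1L + stats::rpois(np, max(0, config$peptidesPerProtein - 1))
  pepProtein <- rep(proteinId, nPep)
  pepId <- paste0(pepProtein, "_pep",
                  unlist(lapply(nPep, seq_len), use.names = FALSE))
  propensity <- stats::rnorm(length(pepId), 0, config$peptideLogSd)
  pepCyto <- cytosolic[match(pepProtein, proteinId)]
  pepMarker <- markerType[match(pepProtein, proteinId)]

  lay <- config$layout
  chTab <- plexChannelNames(lay)
  nCells <- config$nBatches * lay[["single_cell"]]
  cellType <- sample(types, nCells, replace = TRUE,
                     prob = config$typeProportions)
  inputPg <- exp(stats::rnorm(nCells, log(config$cellInputMedianPg),
                              config$cellInputSigma))
  perm <- rep(FALSE, nCells)
  perm[sample.int(nCells, round(config$permFraction * nCells))] <- TRUE

  batches <- sprintf("batch%02d", seq_len(config$nBatches))
  samples <- do.call(rbind, lapply(seq_len(config$nBatches), function(b) {
    data.frame(sample_id = sprintf("%s_%s", batches[b], chTab$channel),
               batch = batches[b], channel = chTab$channel,
               role = chTab$role, stringsAsFactors = FALSE)
  }))
  samples$bridge_pg <- ifelse(samples$role == "bridge", config$bridgePg,
                              NA_real_)
  cellSamples <- samples$sample_id[samples$role == "single_cell"]

  # peptide-level log2 type means and per-cell abundance
  pepTypeMeans <- typeMeans[pepProtein, , drop = FALSE] + propensity
  cellLog2 <- pepTypeMeans[, cellType, drop = FALSE] +
    matrix(stats::rnorm(length(pepId) * nCells, 0, config$cellNoiseSd),
           length(pepId), nCells)
  cellLin <- 2^cellLog2
  # scale each cell to its nominal input, then apply permeabilization leak
  sc <- (inputPg * config$unitsPerPg) / colSums(cellLin)
  cellLin <- sweep(cellLin, 2L, sc, `*`)
  if (any(perm))
    cellLin[pepCyto, perm] <- cellLin[pepCyto, perm] * config$leakFactor
  contentPg <- colSums(cellLin) / config$unitsPerPg

  # bridge profile: population-weighted average proteome, scaled to bridgePg
  popLin <- 2^pepTypeMeans %*% config$typeProportions
  bridgeLin <- popLin / sum(popLin) * config$bridgePg * config$unitsPerPg

  abundance <- matrix(0, length(pepId), nrow(samples),
                      dimnames = list(pepId, samples$sample_id))
  abundance[, cellSamples] <- cellLin
  abundance[, samples$sample_id[samples$role == "bridge"]] <-
    matrix(bridgeLin, length(pepId), sum(samples$role == "bridge"))

  batchLocation <- matrix(stats::rnorm(length(pepId) * config$nBatches, 0,
                                       config$batchLocationSd),
                          length(pepId), config$nBatches,
                          dimnames = list(pepId, batches))
  batchScale <- matrix(exp(stats::rnorm(length(pepId) * config$nBatches, 0,
                                        config$batchScaleSd)),
                       length(pepId), config$nBatches,
                       dimnames = list(pepId, batches))

  cells <- data.frame(sample_id = cellSamples,
                      batch = samples$batch[match(cellSamples,
                                                  samples$sample_id)],
                      channel = samples$channel[match(cellSamples,
                                                      samples$sample_id)],
                      type = cellType, input_pg = inputPg,
                      content_pg = contentPg, permeabilized = perm,
                      stringsAsFactors = FALSE)

  design <- plexDesign(batch = samples$batch, channel = samples$channel,
                       role = samples$role, bridge_pg = samples$bridge_pg)

  out <- list(config = config,
              proteins = data.frame(protein_id = proteinId,
                                    baseline_log2 = baseline,
                                    cytosolic = cytosolic,
                                    marker_type = markerType,
                                    stringsAsFactors = FALSE),
              features = data.frame(peptide_id = pepId,
                                    protein_id = pepProtein,
                                    cytosolic = pepCyto,
                                    marker_type = pepMarker,
                                    stringsAsFactors = FALSE),
              cells = cells, samples = samples, abundance = abundance,
              typeMeans = typeMeans, batchLocation = batchLocation,
              batchScale = batchScale, design = design)
  class(out) <- "GroundTruthDataset"
  out
}

#' @export
print.GroundTruthDataset <- function(x, ...) {
  cat(sprintf(
    "GroundTruthDataset: %d peptides / %d proteins, %d cells in %d batches\n",
    nrow(x$features), nrow(x$proteins), nrow(x$cells),
    x$config$nBatches))
  cat(sprintf("  types: %s\n",
              paste(sprintf("%s=%d", names(table(x$cells$type)),
                            table(x$cells$type)), collapse = ", ")))
  cat(sprintf("  permeabilized: %d (leak %.2f on %.0f%% cytosolic)\n",
              sum(x$cells$permeabilized), x$config$leakFactor,
              100 * x$config$cytosolicFraction))
  invisible(x)
}

#' Configuration for the acquisition simulator
#'
#' Models data-dependent MS2 acquisition with a fixed per-run scan budget.
#' Real peptide features become precursor candidates with probability
#' logistic in their log10 total (plex-summed) abundance; chemical-noise
#' features join the candidate pool and carry no quantifiable reporter
#' signal. In `standard` mode the budget is spent on candidates sampled with
#' intensity bias; in `rtls` mode each candidate is first screened against a
#' spectral library (a real feature passes with probability `tau`, a noise
#' feature with probability `1 - sigma`) and only passing candidates consume
#' budget. Identified features receive per-channel reporter intensities with
#' multiplicative log-normal noise, batch location/scale effects, and a
#' bridge-driven interference term added to every channel; intensities below
#' `reportingLimit` are reported missing.
#'
#' @param mode `"rtls"` (library-gated) or `"standard"`.
#' @param ms2Budget quantitative MS2 scans available per run.
#' @param noiseFraction fraction of the candidate pool that is noise.
#' @param screenSensitivity tau: probability a real candidate passes the
#'   library screen.
#' @param screenSpecificity sigma: probability a noise candidate is rejected.
#' @param obsSlope,obsMidpoint logistic observability model on log10 total
#'   abundance.
#' @param reporterCV coefficient of variation of reporter-ion noise.
#' @param reportingLimit per-channel intensity floor below which a
#'   quantification is reported missing.
#' @param seed integer seed.
#' @return A validated `AcquisitionConfig` (list).
#' @export
acquisitionConfig <- function(mode = c("rtls", "standard"),
                              ms2Budget = 600L, noiseFraction = 0.5,
                              screenSensitivity = 0.95,
                              screenSpecificity = 0.95,
                              obsSlope = 1.5, obsMidpoint = 3.5,
                              reporterCV = 0.2, reportingLimit = 25,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (ms2Budget < 0) stop("ms2Budget must be >= 0")
  if (noiseFraction < 0 || noiseFraction >= 1)
    stop("noiseFraction must lie in [0, 1)")
  if (screenSensitivity < 0 || screenSensitivity > 1 ||
      screenSpecificity < 0 || screenSpecificity > 1)
    stop("screen probabilities must lie in [0, 1]")
  structure(list(mode = mode, ms2Budget = as.integer(ms2Budget),
                 noiseFraction = noiseFraction,
                 screenSensitivity = screenSensitivity,
                 screenSpecificity = screenSpecificity,
                 obsSlope = obsSlope, obsMidpoint = obsMidpoint,
                 reporterCV = reporterCV, reportingLimit = reportingLimit,
                 seed = as.integer(seed)),
            class = "AcquisitionConfig")
}

#' Simulate multiplexed reporter-ion acquisition
#'
#' Runs the acquisition model of [acquisitionConfig()] once per batch of a
#' [generateTruth()] dataset and assembles the observed peptide-level
#' [QuantMatrix-class]. The random streams for candidate detection, noise
#' features, library screening, precursor selection and reporter noise are
#' seeded independently per run, so `standard` and `rtls` runs with the same
#' seed see identical candidate pools and reporter noise (paired
#' comparisons), and increasing a feature's abundance can only move it into
#' the candidate pool, never out of it.
#'
#' @param truth a `GroundTruthDataset`.
#' @param acq an `AcquisitionConfig`.
#' @return A list with `qm` (linear peptide-level [QuantMatrix-class], all
#'   channels), `idSets` (per-run character vectors of identified real
#'   peptides), and `runStats` (per-run candidate/selection counts).
#' @export
simulateAcquisition <- function(truth, acq) {
  if (!inherits(truth, "GroundTruthDataset")) stop("truth must be a GroundTruthDataset")
  if (!inherits(acq, "AcquisitionConfig")) stop("acq must be an AcquisitionConfig")
  if (nrow(truth$features) == 0L) stop("empty truth dataset")
  samples <- truth$samples
  batches <- unique(samples$batch)
  pepId <- truth$features$peptide_id
  nFeat <- length(pepId)
  X <- matrix(NA_real_, nFeat, nrow(samples),
              dimnames = list(pepId, samples$sample_id))
  idSets <- vector("list", length(batches))
  names(idSets) <- batches
  runStats <- data.frame(batch = batches, n_candidates_real = 0L,
                         n_noise = 0L, n_selected = 0L,
                         n_identified_real = 0L)
  sdlog <- sqrt(log(1 + acq$reporterCV^2))

  for (bi in seq_along(batches)) {
    b <- batches[bi]
    cols <- which(samples$batch == b)
    trueA <- truth$abundance[, cols, drop = FALSE]
    totalA <- rowSums(trueA)

    set.seed(stageSeed(acq$seed, paste0("detect:", b)))
    u <- stats::runif(nFeat)
    pDet <- stats::plogis(acq$obsSlope * (log10(totalA + 1) -
                                            acq$obsMidpoint))
    realCand <- which(u < pDet)

    set.seed(stageSeed(acq$seed, paste0("noisefeat:", b)))
    f <- acq$noiseFraction
    nNoise <- if (length(realCand)) round(f / (1 - f) * length(realCand))
              else 0L
    noiseInt <- if (nNoise > 0)
      sample(totalA[realCand], nNoise, replace = TRUE) else numeric()

    set.seed(stageSeed(acq$seed, paste0("screen:", b)))
    realPass <- stats::runif(length(realCand)) < acq$screenSensitivity
    noisePass <- stats::runif(nNoise) < (1 - acq$screenSpecificity)

    candIdx <- c(realCand, rep(NA_integer_, nNoise))   # NA marks noise
    candInt <- c(totalA[realCand], noiseInt)
    keep <- if (acq$mode == "rtls") c(realPass, noisePass)
            else rep(TRUE, length(candIdx))

    set.seed(stageSeed(acq$seed, paste0("select:", b)))
    avail <- which(keep)
    nSel <- min(acq$ms2Budget, length(avail))
    sel <- if (nSel > 0)
      avail[sample.int(length(avail), nSel, prob = candInt[avail])]
      else integer()
    idReal <- candIdx[sel]
    idReal <- idReal[!is.na(idReal)]

    set.seed(stageSeed(acq$seed, paste0("reporter:", b)))
    Z <- matrix(stats::rnorm(nFeat * length(cols)), nFeat, length(cols))
    sdEff <- sdlog * truth$batchScale[, b]
    noiseMat <- exp(Z * sdEff - 0.5 * sdEff^2)
    meas <- trueA * 2^truth$batchLocation[, b] * noiseMat
    bridgeCols <- which(samples$role[cols] == "bridge")
    eps <- truth$config$interferenceEps
    if (length(bridgeCols) && eps > 0) {
      leak <- rowSums(meas[, bridgeCols, drop = FALSE])
      meas <- meas + eps * leak
    }

    if (length(idReal)) {
      obs <- meas[idReal, , drop = FALSE]
      obs[obs < acq$reportingLimit] <- NA
      X[idReal, cols] <- obs
    }
    idSets[[bi]] <- pepId[idReal]
    runStats$n_candidates_real[bi] <- length(realCand)
    runStats$n_noise[bi] <- nNoise
    runStats$n_selected[bi] <- nSel
    runStats$n_identified_real[bi] <- length(idReal)
  }

  meta <- samples
  rowInfo <- truth$features
  names(rowInfo)[names(rowInfo) == "protein_id"] <- "protein"
  qm <- QuantMatrix(X, level = "peptide", scale = "linear",
                    sampleMeta = meta, rowData = rowInfo)
  list(qm = qm, idSets = idSets, runStats = runStats)
}

#' Generate a reference expression dataset for label transfer
#'
#' Builds a transcriptome-style reference (genes x reference cells, log2
#' scale) whose types correspond to the ground-truth types and whose shared
#' gene ids (a configurable fraction of the proteome) track the true protein
#' type means, emulating a subsampled single-cell RNA atlas of the same
#' tissue. Non-shared genes carry their own type structure so the reference
#' has realistic internal variation.
#'
#' @param truth a `GroundTruthDataset`.
#' @param overlapFraction fraction of proteome ids present as gene ids.
#' @param nRefCells number of reference cells (must be >= number of types).
#' @param seed integer seed.
#' @param excludeTypes types absent from the reference (e.g. a contaminating
#'   granulocyte population a blood-cell atlas would not contain).
#' @param nExtraGenes reference-only genes.
#' @param refNoiseSd log2 expression noise SD.
#' @return A `ReferenceExpression` list: `expr` (genes x cells log2),
#'   `labels`, `sharedIds`.
#' @export
generateReference <- function(truth, overlapFraction = 0.6,
                              nRefCells = 500L, seed = 1L,
                              excludeTypes = NULL, nExtraGenes = 400L,
                              refNoiseSd = 0.8) {
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must lie in [0, 1]")
  types <- setdiff(colnames(truth$typeMeans), excludeTypes)
  if (length(types) < 2L) stop("reference needs >= 2 types")
  if (nRefCells < length(types))
    stop("nRefCells must be >= number of reference types")
  set.seed(stageSeed(seed, "reference"))
  protIds <- truth$proteins$protein_id
  nShared <- round(overlapFraction * length(protIds))
  shared <- sort(sample(protIds, nShared))
  extra <- sprintf("G%05d", seq_len(nExtraGenes))

  mu <- truth$typeMeans[shared, types, drop = FALSE]
  extraBase <- stats::rnorm(nExtraGenes, 6, 1.5)
  extraMu <- matrix(extraBase, nExtraGenes, length(types),
                    dimnames = list(extra, types))
  nMark <- round(0.04 * nExtraGenes)
  pool <- seq_len(nExtraGenes)
  for (ty in types) {
    pick <- sample(pool, min(nMark, length(pool)))
    extraMu[pick, ty] <- extraMu[pick, ty] + 2
    pool <- setdiff(pool, pick)
  }
  mu <- rbind(mu, extraMu)

  prop <- truth$config$typeProportions[
    match(types, colnames(truth$typeMeans))]
  prop <- prop / sum(prop)
  labels <- sample(types, nRefCells, replace = TRUE, prob = prop)
  # guarantee every type is represented
  labels[seq_along(types)] <- types
  expr <- mu[, labels, drop = FALSE] +
    matrix(stats::rnorm(nrow(mu) * nRefCells, 0, refNoiseSd),
           nrow(mu), nRefCells)
  colnames(expr) <- sprintf("ref%04d", seq_len(nRefCells))
  structure(list(expr = expr,
                 labels = stats::setNames(labels, colnames(expr)),
                 sharedIds = shared),
            class = "ReferenceExpression")
}

#' @export
print.ReferenceExpression <- function(x, ...) {
  cat(sprintf("ReferenceExpression: %d genes x %d cells, %d types, %d shared ids\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$labels)),
              length(x$sharedIds)))
  invisible(x)
}
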