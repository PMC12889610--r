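test_that("ground truth generation is deterministic and honours the config", {
  tr1 <- smallTruth(seed = 11)
  tr2 <- smallTruth(seed = 11)
  expect_identical(tr1$abundance, tr2$abundance)
  expect_identical(tr1$cells, tr2$cells)

  # layout respected per batch
  rc <- table(tr1$samples$batch, tr1$samples$role)
  expect_true(all(rc[, "bridge"] == 2L))
  expect_true(all(rc[, "blank"] == 1L))
  expect_true(all(rc[, "single_cell"] == 9L))

  # no permeabilization when the fraction is zero
  tr0 <- smallTruth(seed = 3, permFraction = 0)
  expect_false(any(tr0$cells$permeabilized))

  # abundances nonnegative, blanks carry zero true signal
  expect_true(all(tr1$abundance >= 0))
  blanks <- tr1$samples$sample_id[tr1$samples$role == "blank"]
  expect_true(all(tr1$abundance[, blanks] == 0))
})

test_that("marker construction separates type means by the configured effect", {
  tr <- smallTruth(seed = 7, markerLog2Effect = 2)
  for (ty in colnames(tr$typeMeans)) {
    mk <- !is.na(tr$proteins$marker_type) & tr$proteins$marker_type == ty
    expect_true(any(mk))
    others <- setdiff(colnames(tr$typeMeans), ty)
    gaps <- tr$typeMeans[mk, ty] - tr$typeMeans[mk, others, drop = FALSE]
    expect_equal(unname(as.vector(gaps)), rep(2, sum(mk) * length(others)))
  }
  # marker sets are disjoint and equally sized
  counts <- table(tr$proteins$marker_type)
  expect_equal(length(unique(counts)), 1L)
})

test_that("permeabilized cells lose exactly the leaked cytosolic content", {
  tr <- smallTruth(seed = 5)
  lambda <- tr$config$leakFactor
  cyto <- tr$features$cytosolic
  perm <- tr$cells$permeabilized
  expect_true(any(perm))
  # content = nominal input minus leaked cytosolic share
  cells <- tr$cells$sample_id
  A <- tr$abundance[, cells, drop = FALSE]
  got <- colSums(A) / tr$config$unitsPerPg
  expect_equal(got, tr$cells$content_pg, tolerance = 1e-12,
               ignore_attr = TRUE)
  # for permeabilized cells the cytosolic share is scaled by lambda:
  # reconstructing the pre-leak column must recover the nominal input
  pre <- A
  pre[cyto, perm] <- pre[cyto, perm] / lambda
  expect_equal(unname(colSums(pre) / tr$config$unitsPerPg),
               tr$cells$input_pg, tolerance = 1e-9)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(groundTruthConfig(permFraction = 1.5), "fraction")
  expect_error(groundTruthConfig(leakFactor = 1), "leakFactor")
  expect_error(groundTruthConfig(bridgePg = 0), "pg")
  expect_error(groundTruthConfig(nCellTypes = 3,
                                 typeProportions = c(0.5, 0.5)),
               "typeProportions")
  expect_error(acquisitionConfig(ms2Budget = -1), "ms2Budget")
  expect_error(acquisitionConfig(noiseFraction = 1), "noiseFraction")
})

test_that("acquisition is deterministic, budget-limited and mode-aware", {
  tr <- smallTruth(seed = 21)
  acq <- acquisitionConfig(mode = "rtls", seed = 9)
  s1 <- simulateAcquisition(tr, acq)
  s2 <- simulateAcquisition(tr, acq)
  expect_identical(intensities(s1$qm), intensities(s2$qm))
  expect_identical(s1$idSets, s2$idSets)

  # zero budget -> nothing identified, all-missing matrix
  s0 <- simulateAcquisition(tr, acquisitionConfig(ms2Budget = 0, seed = 9))
  expect_true(all(is.na(intensities(s0$qm))))
  expect_equal(sum(lengths(s0$idSets)), 0L)
})

test_that("library gating equals standard selection in the no-noise limit", {
  tr <- smallTruth(seed = 31)
  ids <- lapply(c("rtls", "standard"), function(mode) {
    s <- simulateAcquisition(tr, acquisitionConfig(
      mode = mode, noiseFraction = 0, screenSensitivity = 1,
      screenSpecificity = 1, seed = 4))
    sort(unique(unlist(s$idSets)))
  })
  expect_identical(ids[[1]], ids[[2]])
})

test_that("identification probability increases with feature abundance", {
  tr <- smallTruth(seed = 41, nProteins = 40)
  totalA <- rowSums(tr$abundance)
  freq <- rep(0, nrow(tr$features))
  nSim <- 300L
  for (s in seq_len(nSim)) {
    sim <- simulateAcquisition(tr, acquisitionConfig(
      mode = "standard", ms2Budget = 60L, seed = s))
    idx <- rownames(tr$abundance) %in% unlist(sim$idSets)
    freq <- freq + idx
  }
  # abundance rank should predict identification frequency
  expect_gt(stats::cor(log10(totalA + 1), freq / nSim,
                       method = "spearman"), 0.8)
})

test_that("blank-channel signal above threshold grows with bridge input", {
  counts <- vapply(c(50, 100, 250, 1000), function(bp) {
    tr <- generateTruth(groundTruthConfig(
      nBatches = 1L, nProteins = 150L, bridgePg = bp, seed = 13))
    sim <- simulateAcquisition(tr, acquisitionConfig(seed = 14))
    x <- intensities(sim$qm)
    blanks <- tr$samples$sample_id[tr$samples$role == "blank"]
    sum(x[, blanks] >= 25, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("reference generation respects overlap, exclusions and determinism", {
  tr <- smallTruth(seed = 51)
  r1 <- generateReference(tr, overlapFraction = 0.5, nRefCells = 60,
                          seed = 2)
  r2 <- generateReference(tr, overlapFraction = 0.5, nRefCells = 60,
                          seed = 2)
  expect_identical(r1$expr, r2$expr)
  expect_equal(length(r1$sharedIds), round(0.5 * nrow(tr$proteins)))
  expect_true(all(r1$sharedIds %in% rownames(r1$expr)))

  r0 <- generateReference(tr, overlapFraction = 0, nRefCells = 60,
                          seed = 2)
  expect_length(intersect(rownames(r0$expr), tr$proteins$protein_id), 0)
  rall <- generateReference(tr, overlapFraction = 1, nRefCells = 60,
                            seed = 2)
  expect_true(all(tr$proteins$protein_id %in% rownames(rall$expr)))

  rex <- generateReference(tr, nRefCells = 60, seed = 2,
                           excludeTypes = "T3")
  expect_false("T3" %in% rex$labels)
  expect_error(generateReference(tr, nRefCells = 1), "nRefCells")

  # shared genes track protein type structure
  mk <- tr$proteins$protein_id[!is.na(tr$proteins$marker_type) &
                                 tr$proteins$marker_type == "T1"]
  mk <- intersect(mk, r1$sharedIds)
  if (length(mk)) {
    inT1 <- rowMeans(r1$expr[mk, r1$labels == "T1", drop = FALSE])
    inT2 <- rowMeans(r1$expr[mk, r1$labels == "T2", drop = FALSE])
    expect_gt(mean(inT1 - inT2), 1)
  }
})
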