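test_that("channel sums count observed features and flag empty samples", {
  qm <- tinyQuant()
  cs <- channelSums(qm)
  expect_equal(cs$sum_intensity, c(18, 28, 12, 9))
  expect_equal(cs$n_features, c(3L, 2L, 2L, 2L))
  expect_false(any(cs$all_missing))

  m <- matrix(c(1, 2, NA, NA), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cs2 <- channelSums(QuantMatrix(m))
  expect_equal(cs2$sum_intensity, c(3, 0))
  expect_true(cs2$all_missing[2])

  # feature order is irrelevant
  perm <- qm[c(3, 1, 2), ]
  expect_equal(channelSums(perm)$sum_intensity, cs$sum_intensity)

  expect_error(channelSums(toLog2(qm)), "linear")
})

test_that("fold differences follow the median-ratio definition", {
  mk <- function(role, sums) data.frame(role = role, sum_intensity = sums)
  s <- rbind(mk("bridge", c(1000, 1100)), mk("single_cell", c(90, 100, 110)),
             mk("blank", c(0.25, 0.5)))
  fd <- foldDifferences(s)
  expect_equal(fd$bridge_vs_cell, 1050 / 100)
  expect_equal(fd$cell_vs_blank, 100 / 0.375)

  s2 <- rbind(mk("single_cell", 380), mk("blank", 1))
  expect_equal(foldDifferences(s2)$cell_vs_blank, 380)

  # blanks absent by design: undefined, not an error
  s3 <- rbind(mk("bridge", 1000), mk("single_cell", 100))
  expect_true(is.na(foldDifferences(s3)$cell_vs_blank))
  expect_equal(foldDifferences(s3)$bridge_vs_cell, 10)

  s4 <- rbind(mk("single_cell", 100), mk("blank", 0))
  expect_error(foldDifferences(s4), "zero median")
})

test_that("input back-calculation matches the bridge-ratio formula", {
  design <- plexDesign(batch = rep("b1", 4),
                       channel = c("126", "135ND", "127N", "127C"),
                       role = c("bridge", "bridge", "single_cell",
                                "single_cell"),
                       bridge_pg = c(150, 150, NA, NA))
  s <- data.frame(sample_id = paste0("s", 1:4), batch = "b1",
                  channel = c("126", "135ND", "127N", "127C"),
                  role = c("bridge", "bridge", "single_cell",
                           "single_cell"),
                  sum_intensity = c(900, 1100, 100, 0),
                  n_features = c(10L, 10L, 5L, 0L))
  est <- estimateInput(s, design)
  expect_equal(est$est_input_pg[3], 150 * 100 / 1000)  # 15 pg
  expect_equal(est$est_input_pg[4], 0)
  expect_true(all(is.na(est$est_input_pg[1:2])))

  # a cohort whose cell:bridge fold is 10.5 implies 150/10.5 pg
  s$sum_intensity[3] <- 1000 / 10.5
  est2 <- estimateInput(s, design)
  expect_equal(est2$est_input_pg[3], 150 / 10.5, tolerance = 1e-12)

  sNoBridge <- s[s$role != "bridge", ]
  expect_error(estimateInput(sNoBridge, design), "bridge")
})

test_that("completeness ignores never-observed features", {
  m <- matrix(NA_real_, 3, 4, dimnames = list(paste0("f", 1:3),
                                              paste0("s", 1:4)))
  m[1, 1:3] <- 1; m[2, 1:2] <- 1; m[3, 4] <- 1
  qm <- QuantMatrix(m)
  expect_equal(completeness(qm), 6 / 12)
  full <- QuantMatrix(matrix(1, 2, 2,
                             dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(completeness(full), 1)

  # an all-missing feature leaves the value unchanged
  m2 <- rbind(m, f4 = NA_real_)
  expect_equal(completeness(QuantMatrix(m2)), 6 / 12)
  expect_error(completeness(qm, character()), "empty")
  expect_error(completeness(qm, "nope"), "unknown")
})

test_that("sensitivity curves aggregate unique identifications correctly", {
  runs <- list(c("p1", "p2"), c("p2", "p3"), c("p3", "p4"))
  sc <- sensitivityCurve(runs, nPerm = 0)
  expect_equal(sc$cumulative, c(2, 3, 4))
  expect_equal(sc$total, 4)
  expect_equal(sc$meanLocal, 2)

  # identical runs give a flat curve
  flat <- sensitivityCurve(list(c("a", "b"), c("a", "b")), nPerm = 0)
  expect_equal(flat$cumulative, c(2, 2))

  # exact average over all 6 orderings at k = 2: enumerate ordered pairs
  ex <- sensitivityCurve(runs, exact = TRUE)
  pairUnions <- c(3, 4, 3, 3, 4, 3)    # (1,2) (1,3) (2,1) (2,3) (3,1) (3,2)
  expect_equal(ex$cumulative[2], mean(pairUnions))
  expect_equal(ex$cumulative[1], 2)
  expect_equal(ex$cumulative[3], 4)

  # sampled curves are non-decreasing and bounded by the union
  tr <- smallTruth(seed = 61)
  sim <- simulateAcquisition(tr, acquisitionConfig(seed = 62))
  curve <- sensitivityCurve(sim$idSets, nPerm = 25, seed = 1)
  expect_true(all(diff(curve$cumulative) >= 0))
  expect_gte(curve$total, max(curve$perRun))
  expect_gte(max(curve$perRun), curve$meanLocal)
  expect_error(sensitivityCurve(list()), "no runs")
})

test_that("input estimates track true detectable content on simulated cells", {
  tr <- generateTruth(groundTruthConfig(nBatches = 4L,
                                        interferenceEps = 0, seed = 71))
  sim <- simulateAcquisition(tr, acquisitionConfig(reporterCV = 0.1,
                                                   seed = 72))
  cs <- estimateInput(channelSums(aggregateProteins(sim$qm)), tr$design)
  cells <- cs$role == "single_cell"
  truec <- tr$cells$content_pg[match(cs$sample_id[cells],
                                     tr$cells$sample_id)]
  relerr <- abs(cs$est_input_pg[cells] - truec) / truec
  expect_lte(stats::median(relerr), 0.10)
})
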