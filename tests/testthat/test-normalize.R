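logQM <- function(m, meta = NULL) {
  QuantMatrix(m, level = "protein", scale = "log2", sampleMeta = meta)
}

test_that("median normalization aligns column medians and is idempotent", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("f", 1:3)
  qm <- logQM(m)
  out <- intensities(medianNormalize(qm))
  expect_equal(unname(out[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "s2"]), c(2.5, 3.5, 4.5))

  one <- logQM(matrix(c(1, 5, 9), 3, 1,
                      dimnames = list(paste0("f", 1:3), "s1")))
  expect_equal(intensities(medianNormalize(one)), intensities(one))

  qm2 <- medianNormalize(qm)
  expect_equal(intensities(medianNormalize(qm2)), intensities(qm2))

  # missing cells stay missing, and all-missing samples error
  m[2, 1] <- NA
  out2 <- intensities(medianNormalize(logQM(m)))
  expect_true(is.na(out2[2, 1]))
  m[, 1] <- NA
  expect_error(medianNormalize(logQM(m)), "without observations")
})

test_that("batch correction removes an exact location shift", {
  set.seed(1)
  nf <- 40; n <- 10
  pattern <- stats::rnorm(n)
  mu <- stats::rnorm(nf, 5, 2)
  b1 <- outer(mu, pattern, `+`)
  b2 <- b1 + 0.7
  m <- cbind(b1, b2)
  dimnames(m) <- list(sprintf("f%02d", 1:nf), sprintf("s%02d", 1:(2 * n)))
  meta <- data.frame(sample_id = colnames(m),
                     batch = rep(c("A", "B"), each = n))
  res <- combatAdjust(logQM(m, meta))
  adj <- intensities(res$qm)
  gap <- rowMeans(adj[, 1:n]) - rowMeans(adj[, (n + 1):(2 * n)])
  expect_lt(max(abs(gap)), 1e-6)
  # single batch: output equals input
  one <- combatAdjust(logQM(m[, 1:n],
                            meta[1:n, , drop = FALSE]))
  expect_equal(intensities(one$qm), m[, 1:n], tolerance = 1e-8)
})

test_that("batch correction agrees with the reference implementation on complete data", {
  skip_if_not_installed("sva")
  set.seed(42)
  nf <- 60; n <- 12
  m <- matrix(stats::rnorm(nf * 2 * n, 8, 1), nf, 2 * n,
              dimnames = list(sprintf("f%02d", 1:nf),
                              sprintf("s%02d", 1:(2 * n))))
  batch <- rep(c("A", "B"), each = n)
  m[, batch == "B"] <- m[, batch == "B"] +
    stats::rnorm(nf, 0.8, 0.5)            # per-feature location effects
  m[, batch == "B"] <- m[, batch == "B"] * 1.1
  meta <- data.frame(sample_id = colnames(m), batch = batch)
  mine <- intensities(combatAdjust(logQM(m, meta))$qm)
  ref <- suppressMessages(sva::ComBat(m, batch = batch))
  expect_equal(mine, ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("simulated batch effects are removed and estimates shrink sensibly", {
  set.seed(7)
  nf <- 200; n <- 50
  base <- matrix(stats::rnorm(nf * 2 * n, 10, 1), nf, 2 * n,
                 dimnames = list(sprintf("f%03d", 1:nf),
                                 sprintf("s%03d", 1:(2 * n))))
  batch <- rep(c("A", "B"), each = n)
  gam <- stats::rnorm(nf, 0, 1)
  del <- exp(stats::rnorm(nf, 0, 0.3))
  base[, batch == "B"] <- sweep(sweep(base[, batch == "B"] - 10, 1, del,
                                      `*`), 1, gam + 10, `+`)
  meta <- data.frame(sample_id = colnames(base), batch = batch)
  res <- combatAdjust(logQM(base, meta))
  adj <- intensities(res$qm)
  r2 <- vapply(seq_len(nf), function(g) {
    summary(stats::lm(adj[g, ] ~ batch))$r.squared
  }, numeric(1))
  expect_lt(mean(r2), 0.01)

  # missing values pass through untouched as missing
  holey <- base
  holey[sample.int(length(holey), 500)] <- NA
  resH <- combatAdjust(logQM(holey, meta))
  expect_identical(is.na(intensities(resH$qm)), is.na(holey))
})

test_that("location-only correction preserves within-batch sample order", {
  set.seed(9)
  nf <- 30; n <- 8
  m <- matrix(stats::rnorm(nf * 2 * n, 6, 1), nf, 2 * n,
              dimnames = list(sprintf("f%02d", 1:nf),
                              sprintf("s%02d", 1:(2 * n))))
  batch <- rep(c("A", "B"), each = n)
  m[, batch == "B"] <- m[, batch == "B"] + stats::rnorm(nf, 0, 1)
  meta <- data.frame(sample_id = colnames(m), batch = batch)
  qmN <- medianNormalize(logQM(m, meta))
  adj <- intensities(combatAdjust(qmN)$qm)
  pre <- intensities(qmN)
  for (b in c("A", "B")) {
    cols <- which(batch == b)
    for (g in sample.int(nf, 10))
      expect_equal(order(adj[g, cols]), order(pre[g, cols]))
  }
})

test_that("single-sample batches error unless explicitly passed through", {
  m <- matrix(stats::rnorm(30), 10, 3,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:3)))
  meta <- data.frame(sample_id = colnames(m), batch = c("A", "A", "B"))
  expect_error(combatAdjust(logQM(m, meta)), "single sample")
  expect_warning(res <- combatAdjust(logQM(m, meta), allowSingle = TRUE),
                 "passed through")
  expect_equal(intensities(res$qm)[, 3], m[, 3])
})

test_that("imputation fills only missing cells and respects the floor", {
  m <- matrix(c(1, 1, 2,
                2, 2, NA,
                3, 3, 5,
                NA, NA, NA), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  m[4, 1] <- 9   # f4 observed in 1/3 of samples: barely passes floor 0.3
  qm <- logQM(m)
  # k = 1 with a duplicated column: missing cell copied from the duplicate
  out <- imputeMissing(qm, k = 1, minObsRate = 0.3)
  x <- intensities(out)
  expect_false(anyNA(x))
  expect_equal(x["f2", "s3"], 2)    # s3's nearest neighbour observes f2 = 2
  # observed values untouched
  obs <- !is.na(m[rownames(x), ])
  expect_identical(x[obs], m[rownames(x), ][obs])
  expect_identical(S4Vectors::metadata(out)$imputedMask,
                   is.na(m[rownames(x), ]))

  # complete matrix passes through unchanged
  full <- logQM(m[1:1, , drop = FALSE])
  expect_identical(intensities(imputeMissing(full)), m[1, , drop = FALSE])

  # floor drops sparsely observed features
  dropped <- imputeMissing(qm, k = 1, minObsRate = 0.5)
  expect_false("f4" %in% rownames(dropped))

  # minprob draws below the observed distribution, deterministically by seed
  mp1 <- imputeMissing(qm, method = "minprob", seed = 3)
  mp2 <- imputeMissing(qm, method = "minprob", seed = 3)
  expect_identical(intensities(mp1), intensities(mp2))
})
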