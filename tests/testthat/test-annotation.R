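test_that("PCA embedding is deterministic with a fixed sign convention", {
  set.seed(2)
  x <- matrix(stats::rnorm(200), 10, 20,
              dimnames = list(paste0("f", 1:10), paste0("c", 1:20)))
  qm <- QuantMatrix(x, scale = "log2")
  e1 <- pcaEmbed(qm, nPcs = 3)
  e2 <- pcaEmbed(qm, nPcs = 3)
  expect_identical(e1, e2)
  # sign convention: dominant loading positive on every component
  rot <- attr(e1, "rotation")
  for (j in 1:3)
    expect_gt(rot[which.max(abs(rot[, j])), j], 0)

  # collinear features: PC1 carries all variance
  y <- rbind(f1 = stats::rnorm(15), deparse.level = 1)
  y <- rbind(f1 = y[1, ], f2 = 2 * y[1, ])
  colnames(y) <- paste0("c", 1:15)
  emb <- pcaEmbed(QuantMatrix(y, scale = "log2"), nPcs = 1)
  expect_equal(attr(emb, "varExplained")[1], 1)

  expect_error(pcaEmbed(qm, nPcs = 0), "nPcs")
  expect_error(pcaEmbed(qm, nPcs = 50), "exceeds")
})

test_that("SNN graph follows the Jaccard rule and prunes weak edges", {
  # two points, k = 1: neighbour sets {b} and {a}, Jaccard 0, pruned
  emb <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  g <- snnGraph(emb, k = 1)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 0)
  # with prune = 0 the kNN edge is retained at weight 0
  g0 <- snnGraph(emb, k = 1, prune = 0)
  expect_equal(igraph::ecount(g0), 1)
  expect_equal(igraph::E(g0)$weight, 0)

  # two well-separated blobs never connect
  set.seed(5)
  blob <- rbind(matrix(stats::rnorm(20, 0, 0.5), 10),
                matrix(stats::rnorm(20, 50, 0.5), 10))
  rownames(blob) <- paste0("c", 1:20)
  gb <- snnGraph(blob, k = 3)
  el <- igraph::as_edgelist(gb, names = FALSE)
  side <- function(i) ifelse(i <= 10, 1L, 2L)
  expect_true(all(side(el[, 1]) == side(el[, 2])))

  expect_error(snnGraph(blob, k = 0), "positive")
  expect_error(snnGraph(blob, k = 20), "smaller")
})

test_that("Louvain matches the brute-force modularity optimum on bridged cliques", {
  g <- bridgedCliques()
  # exhaustive search over all partitions of the 8 vertices
  parts <- allPartitions(8)
  mods <- vapply(parts, function(p) igraph::modularity(g, p), numeric(1))
  best <- parts[[which.max(mods)]]
  expect_equal(length(unique(best)), 2L)
  expect_equal(best[1:4], rep(best[1], 4))
  expect_equal(best[5:8], rep(best[5], 4))

  cl <- louvainCluster(g, resolution = 1, seed = 1)
  expect_equal(igraph::modularity(g, cl$clusters), max(mods),
               tolerance = 1e-12)
  expect_equal(length(unique(cl$clusters)), 2L)

  # complete graph collapses to one community
  kg <- igraph::make_full_graph(6)
  igraph::V(kg)$name <- paste0("v", 1:6)
  expect_equal(length(unique(louvainCluster(kg, seed = 1)$clusters)), 1L)

  # determinism
  cl2 <- louvainCluster(g, resolution = 1, seed = 1)
  expect_identical(cl$clusters, cl2$clusters)
  expect_error(louvainCluster(igraph::make_empty_graph(0,
                                                       directed = FALSE)),
               "empty")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  expect_equal(hyperEnrichmentP(4, 10, 5, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hyperEnrichmentP(0, 10, 5, 4), 1)
  # K = N: every draw is that type, no enrichment possible
  expect_equal(hyperEnrichmentP(3, 8, 8, 3), 1)
  expect_error(hyperEnrichmentP(5, 10, 4, 8), "k must lie")

  for (N in c(5, 9, 12)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hyperEnrichmentP(k, N, K, n), hyperOracle(k, N, K, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("cluster enrichment labels clusters and propagates to all cells", {
  # 2 clusters; cluster 1 dominated by type A, cluster 2 by B, plus
  # low-confidence cells that must inherit the cluster label
  cells <- sprintf("c%02d", 1:24)
  clusters <- stats::setNames(rep(1:2, each = 12L), cells)
  s <- matrix(0.5, 24, 2, dimnames = list(cells, c("A", "B")))
  s[1:10, ] <- rep(c(0.95, 0.05), each = 10)       # confident A
  s[13:22, ] <- rep(c(0.05, 0.95), each = 10)      # confident B
  ps <- predictionScores(s)
  expect_true(all(!highConfidence(ps)[c(11, 12, 23, 24)]))
  ann <- clusterEnrichment(clusters, ps, alpha = 0.05)
  expect_identical(unname(clusterLabels(ann)), c("A", "B"))
  expect_identical(unname(cellLabels(ann)[c("c11", "c12")]), c("A", "A"))
  expect_identical(unname(cellLabels(ann)[c("c23", "c24")]), c("B", "B"))
  tab <- enrichmentTable(ann)
  expect_true(all(tab$p_adj >= tab$p))
  expect_true(all(tab$k <= pmin(tab$K, tab$n)))

  # uninformative scores: types spread evenly, clusters stay unknown
  sFlat <- matrix(rep(c(0.51, 0.49, 0.49, 0.51), 12), 24, 2, byrow = TRUE,
                  dimnames = list(cells, c("A", "B")))
  annU <- clusterEnrichment(clusters, predictionScores(sFlat),
                            alpha = 0.05)
  expect_true(all(clusterLabels(annU) == "unknown"))
})

test_that("permeabilized-cluster flagging requires all three gates", {
  set.seed(12)
  mkSummary <- function(ids, input, nid) {
    data.frame(sample_id = ids, est_input_pg = input, n_features = nid)
  }
  # clusters 1 and 2 share label A; cluster 3 is the B background that
  # makes the enrichment test informative
  cells <- sprintf("c%03d", 1:200)
  clusters <- stats::setNames(rep(1:3, c(50L, 50L, 100L)), cells)
  isA <- c(rep(TRUE, 45), rep(FALSE, 5), rep(TRUE, 45), rep(FALSE, 5),
           rep(FALSE, 90), rep(TRUE, 10))
  s <- cbind(A = ifelse(isA, 0.9, 0.1), B = ifelse(isA, 0.1, 0.9))
  rownames(s) <- cells
  ps <- predictionScores(s)
  ann <- clusterEnrichment(clusters, ps)
  expect_identical(unname(clusterLabels(ann)), c("A", "A", "B"))

  # identical distributions: nothing flagged
  inputSame <- exp(stats::rnorm(200, log(14), 0.3))
  nidSame <- stats::rpois(200, 200)
  res <- flagPermeabilized(ann, mkSummary(cells, inputSame, nidSame), ps)
  expect_length(res$flaggedClusters, 0)
  expect_equal(nrow(res$report), 1)

  # a genuinely leaky second cluster: lower input AND lower ids
  low <- clusters == 2L
  inputPerm <- inputSame
  inputPerm[low] <- inputPerm[low] * 0.55
  nidPerm <- nidSame
  nidPerm[low] <- nidPerm[low] - 60L
  res2 <- flagPermeabilized(ann, mkSummary(cells, inputPerm, nidPerm), ps)
  expect_identical(res2$flaggedClusters, 2L)
  expect_identical(res2$flaggedCells, cells[low])
  expect_true(all(res2$report$flagged_cluster %in% c(NA, 2L)))

  # low input alone (ids indistinguishable) must not flag
  res3 <- flagPermeabilized(ann, mkSummary(cells, inputPerm, nidSame), ps)
  expect_length(res3$flaggedClusters, 0)

  # clusters of different labels are never compared
  res4 <- flagPermeabilized(ann, mkSummary(cells, inputPerm, nidPerm), ps)
  expect_false(any(res4$report$label == "B"))
})

test_that("generator-to-flagging round trip detects a planted leaky subpopulation", {
  # same-type clusters of ~100 cells split by the permeabilization flag;
  # the permeabilized half leaks 60% of cytosolic content (lambda 0.4).
  # A tight input distribution keeps the planted effect clearly above the
  # flagging gates so the mechanism itself is what is tested.
  tr <- generateTruth(groundTruthConfig(
    nBatches = 8L, nCellTypes = 2L, typeProportions = c(0.5, 0.5),
    permFraction = 0.5, cellInputSigma = 0.15,
    layout = c(bridge = 2L, blank = 1L, single_cell = 25L),
    seed = 123))
  sim <- simulateAcquisition(tr, acquisitionConfig(seed = 124))
  cs <- estimateInput(channelSums(aggregateProteins(sim$qm)), tr$design)
  perm <- tr$cells$permeabilized
  t1 <- tr$cells$type == "T1"
  ids <- c(tr$cells$sample_id[t1 & !perm], tr$cells$sample_id[t1 & perm],
           tr$cells$sample_id[!t1])
  clusters <- stats::setNames(
    rep(1:3, c(sum(t1 & !perm), sum(t1 & perm), sum(!t1))), ids)
  isT1 <- clusters <= 2L
  s <- cbind(T1 = ifelse(isT1, 0.9, 0.1), T2 = ifelse(isT1, 0.1, 0.9))
  rownames(s) <- ids
  ps <- predictionScores(s)
  ann <- clusterEnrichment(clusters, ps)
  expect_identical(unname(clusterLabels(ann)), c("T1", "T1", "T2"))
  res <- flagPermeabilized(ann, cs, ps)
  expect_true(2L %in% res$flaggedClusters)
  rep1 <- res$report[res$report$label == "T1", ]
  expect_lt(rep1$p_input, 0.01)
  expect_lt(rep1$p_ids, 0.01)
})
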