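#' PCA embedding of cells on selected features
#'
#' Centers (and by default unit-scales) each feature, then computes a PCA of
#' the cells. Deterministic: component signs follow the convention that the
#' loading with the largest magnitude on each component is positive.
#' Zero-variance features are dropped with a warning.
#'
#' @param qm a complete log2 [QuantMatrix-class] (or features x cells
#'   matrix).
#' @param features feature ids to use (e.g. from [selectHVF()]); `NULL` uses
#'   all.
#' @param nPcs number of components (must not exceed `min(dim)`).
#' @param scale unit-scale features before the PCA.
#' @return cells x nPcs matrix with attributes `varExplained` and
#'   `rotation`.
#' @export
pcaEmbed <- function(qm, features = NULL, nPcs = 30L, scale = TRUE) {
  x <- if (is(qm, "QuantMatrix")) intensities(qm) else as.matrix(qm)
  if (anyNA(x)) stop("pcaEmbed needs a complete matrix; impute first")
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(x))
    if (length(missing))
      stop("unknown feature(s): ", paste(utils::head(missing, 5L),
                                         collapse = ", "))
    x <- x[features, , drop = FALSE]
  }
  if (nPcs < 1L) stop("nPcs must be >= 1")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) dropped before PCA")
    x <- x[v > 0, , drop = FALSE]
  }
  maxPcs <- min(nrow(x), ncol(x) - 1L)
  if (nPcs > maxPcs)
    stop("nPcs exceeds min(features, cells - 1) = ", maxPcs)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale)
  emb <- pc$x[, seq_len(nPcs), drop = FALSE]
  rot <- pc$rotation[, seq_len(nPcs), drop = FALSE]
  flip <- vapply(seq_len(nPcs), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1L))
  emb[, flip] <- -emb[, flip]
  rot[, flip] <- -rot[, flip]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(emb, "varExplained") <- ve[seq_len(nPcs)]
  attr(emb, "rotation") <- rot
  emb
}

#' Shared-nearest-neighbor graph
#'
#' Builds the k-nearest-neighbor sets of each cell (Euclidean distance in
#' the embedding, self excluded), connects every pair in which at least one
#' member lists the other among its neighbors, weights each edge by the
#' Jaccard overlap of the two neighbor sets, and removes edges with weight
#' below `prune`. All cells remain vertices, so isolated cells stay in the
#' graph.
#'
#' @param embedding cells x dims matrix (rows named by cell id).
#' @param k neighbors per cell (`0 < k < n`).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @return a weighted undirected [igraph::graph] with vertex names.
#' @export
snnGraph <- function(embedding, k = 20L, prune = 1 / 15) {
  n <- nrow(embedding)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  edges <- integer(); weights <- numeric()
  for (i in seq_len(n)) {
    for (j in nn[[i]]) {
      if (j < i && i %in% nn[[j]]) next    # mutual pair added from j's side
      inter <- length(intersect(nn[[i]], nn[[j]]))
      uni <- length(union(nn[[i]], nn[[j]]))
      w <- inter / uni
      if (w >= prune) {
        edges <- c(edges, min(i, j), max(i, j))
        weights <- c(weights, w)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(edges))
    g <- igraph::add_edges(g, edges, weight = weights)
  g
}

#' Louvain community detection
#'
#' Modularity-maximizing Louvain clustering of the SNN graph at a given
#' resolution. Cluster ids are renumbered densely by decreasing size;
#' isolated vertices become singleton clusters. Deterministic given the
#' seed.
#'
#' @param graph weighted undirected [igraph::graph].
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @return list with `clusters` (named integer vector, dense ids from 1)
#'   and `modularity`.
#' @export
louvainCluster <- function(graph, resolution = 1, seed = 1L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  mem <- igraph::membership(cl)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  clusters <- as.integer(relabel[as.character(mem)])
  names(clusters) <- igraph::V(graph)$name
  list(clusters = clusters,
       modularity = max(cl$modularity %||% igraph::modularity(cl)))
}

#' Hypergeometric tail probability of cluster/type overlap
#'
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`: among `N` high-confidence
#' cells of which `K` carry a given predicted type, the probability that a
#' cluster of `n` such cells contains at least the observed `k` of that
#' type.
#'
#' @param k observed overlap; `N` population; `K` type total; `n` cluster
#'   size.
#' @param N,K,n see above.
#' @return upper-tail probability in (0, 1].
#' @export
hyperEnrichmentP <- function(k, N, K, n) {
  if (k > min(K, n) || k < 0) stop("k must lie in [0, min(K, n)]")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Cluster-level cell-type annotation by hypergeometric enrichment
#'
#' For every (cluster, predicted type) pair, tests whether high-confidence
#' cells of that type are over-represented in the cluster using the
#' hypergeometric upper-tail probability, adjusts p-values across the whole
#' cluster-by-type grid, assigns each cluster the qualifying type with the
#' smallest adjusted p (ties broken by larger overlap `k`, then
#' lexicographic type name), or `"unknown"` when no type passes `alpha`.
#' The cluster label is propagated to **all** member cells, including cells
#' below the confidence cutoff; clusters without any high-confidence cell
#' are labeled `"unknown"` with a warning.
#'
#' @param clusters named integer vector of per-cell cluster ids (see
#'   [louvainCluster()]).
#' @param scores a [PredictionScores-class] covering the same cells.
#' @param alpha significance level on adjusted p-values.
#' @param mtMethod multiple-testing method across the grid (see
#'   [stats::p.adjust]); Benjamini-Hochberg by default.
#' @return a [ClusterAnnotation-class].
#' @export
clusterEnrichment <- function(clusters, scores, alpha = 0.05,
                              mtMethod = "BH") {
  cells <- names(clusters)
  hc <- highConfidence(scores)[cells]
  pred <- predictedType(scores)[cells]
  if (!any(hc, na.rm = TRUE))
    stop("no high-confidence cells available for enrichment")
  hcCells <- cells[hc %in% TRUE]
  N <- length(hcCells)
  types <- sort(unique(pred[hcCells]))
  ks <- sort(unique(clusters))
  grid <- expand.grid(cluster = ks, type = types,
                      stringsAsFactors = FALSE)
  grid$N <- N
  grid$K <- vapply(grid$type,
                   function(t) sum(pred[hcCells] == t), integer(1L))
  grid$n <- vapply(grid$cluster,
                   function(c) sum(clusters[hcCells] == c), integer(1L))
  grid$k <- mapply(function(c, t)
    sum(clusters[hcCells] == c & pred[hcCells] == t),
    grid$cluster, grid$type)
  grid$p <- mapply(hyperEnrichmentP, grid$k, grid$N, grid$K, grid$n)
  grid$p_adj <- stats::p.adjust(grid$p, method = mtMethod)

  labels <- stats::setNames(rep("unknown", length(ks)), ks)
  for (c in ks) {
    sub <- grid[grid$cluster == c & grid$p_adj < alpha, , drop = FALSE]
    if (grid$n[grid$cluster == c][1L] == 0L) {
      warning("cluster ", c, " has no high-confidence cells; ",
              "labeled 'unknown'")
      next
    }
    if (!nrow(sub)) next
    sub <- sub[order(sub$p_adj, -sub$k, sub$type), , drop = FALSE]
    labels[as.character(c)] <- sub$type[1L]
  }
  cellLab <- unname(labels[as.character(clusters)])
  names(cellLab) <- cells
  new("ClusterAnnotation", clusters = clusters, enrichment = grid,
      clusterLabels = labels, cellLabels = cellLab)
}

#' Detect permeabilized-cell clusters
#'
#' Cells that lose cytosolic protein content through unintentional
#' permeabilization before isolation show up as a second, lower-input
#' cluster of an otherwise identical cell type. For every pair of clusters
#' sharing a label, the lower-median-input member is flagged when (1) its
#' median estimated input is at most `rMax` times the higher cluster's, and
#' rank-sum tests reject equality of (2) the estimated inputs and (3) the
#' per-cell identification counts at `pThresh`. Prediction-score
#' distributions per cluster are reported as a diagnostic but do not gate
#' the flag.
#'
#' @param annotation a [ClusterAnnotation-class].
#' @param summary per-sample QC table from [estimateInput()] (columns
#'   `sample_id`, `est_input_pg`, `n_features`).
#' @param scores a [PredictionScores-class] (diagnostic score summaries).
#' @param rMax maximum median-input ratio (low/high) for flagging.
#' @param pThresh rank-sum p-value threshold applied to both gating
#'   metrics.
#' @return list with `report` (one row per same-label cluster pair),
#'   `flaggedClusters` and `flaggedCells`.
#' @export
flagPermeabilized <- function(annotation, summary, scores, rMax = 0.67,
                              pThresh = 0.01) {
  clusters <- cellClusters(annotation)
  labels <- clusterLabels(annotation)
  cells <- names(clusters)
  idx <- match(cells, summary$sample_id)
  if (anyNA(idx))
    stop("QC summary lacks cell(s): ",
         paste(cells[is.na(idx)], collapse = ", "))
  input <- summary$est_input_pg[idx]
  nid <- summary$n_features[idx]
  mx <- maxScores(scores)[cells]

  report <- NULL
  flagged <- integer()
  for (lab in setdiff(unique(labels), "unknown")) {
    ks <- as.integer(names(labels)[labels == lab])
    if (length(ks) < 2L) next
    pairs <- utils::combn(ks, 2L)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      ia <- input[clusters == a]; ib <- input[clusters == b]
      if (stats::median(ia) > stats::median(ib)) { tmp <- a; a <- b; b <- tmp
        tmp <- ia; ia <- ib; ib <- tmp }
      # a is now the lower-input cluster
      na <- nid[clusters == a]; nb <- nid[clusters == b]
      ratio <- stats::median(ia) / stats::median(ib)
      pInput <- suppressWarnings(
        stats::wilcox.test(ia, ib)$p.value)
      pIds <- suppressWarnings(stats::wilcox.test(na, nb)$p.value)
      flag <- isTRUE(ratio <= rMax && pInput < pThresh && pIds < pThresh)
      report <- rbind(report, data.frame(
        label = lab, cluster_low = a, cluster_high = b,
        median_input_low = stats::median(ia),
        median_input_high = stats::median(ib),
        input_ratio = ratio, p_input = pInput,
        median_ids_low = stats::median(na),
        median_ids_high = stats::median(nb), p_ids = pIds,
        median_score_low = stats::median(mx[clusters == a]),
        median_score_high = stats::median(mx[clusters == b]),
        flagged_cluster = if (flag) a else NA_integer_,
        stringsAsFactors = FALSE))
      if (flag) flagged <- union(flagged, a)
    }
  }
  flaggedCells <- cells[clusters %in% flagged]
  list(report = report %||% data.frame(),
       flaggedClusters = flagged, flaggedCells = flaggedCells)
}
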