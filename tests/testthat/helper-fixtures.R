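# Shared fixture builders. Everything is generated in code; no files.

quiet <- function(expr) {
  withr::with_options(list(plexcell.verbose = FALSE), expr)
}

# small wide matrix with metadata for io/qc tests
tinyQuant <- function() {
  m <- matrix(c(10, 20, NA, 5,
                1,  NA, 3,  4,
                7,  8,  9,  NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"),
                              c("s1", "s2", "s3", "s4")))
  meta <- data.frame(sample_id = colnames(m), batch = "b1",
                     channel = c("126", "127N", "127C", "128N"),
                     role = c("bridge", "single_cell", "single_cell",
                              "blank"),
                     stringsAsFactors = FALSE)
  QuantMatrix(m, level = "protein", scale = "linear", sampleMeta = meta)
}

# small ground truth + acquisition for generator round trips
smallTruth <- function(seed = 11, nProteins = 80L, ...) {
  generateTruth(groundTruthConfig(
    nBatches = 2L, nProteins = nProteins, nCellTypes = 3L,
    typeProportions = c(0.5, 0.3, 0.2),
    layout = c(bridge = 2L, blank = 1L, single_cell = 9L),
    seed = seed, ...))
}

# exact hypergeometric upper tail by enumeration of the overlap pmf
hyperOracle <- function(k, N, K, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# all set partitions of n items as membership vectors (restricted growth)
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (g in seq_len(maxUsed + 1L))
      rec(c(prefix, g), max(maxUsed, g))
  }
  rec(integer(), 0L)
  out
}

# two 4-cliques joined by a single bridge edge
bridgedCliques <- function() {
  el <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  igraph::graph_from_edgelist(el, directed = FALSE)
}
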