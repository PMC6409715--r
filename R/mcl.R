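## Markov clustering (MCL) of a weighted undirected graph.

#' Markov clustering
#'
#' Classic MCL: the weighted adjacency matrix (self-loops added) is made
#' column-stochastic and then alternately expanded (matrix squaring) and
#' inflated (entrywise power followed by column renormalization) until
#' the flow matrix stabilizes. Clusters are read off the converged
#' matrix as the connected components of its non-zero structure, so
#' every node lands in exactly one cluster; clusters are ordered (and
#' ties broken) by their lexicographically smallest node id.
#'
#' @param graph An undirected weighted [igraph::igraph] (as produced by
#'   [buildSimilarityGraph()]) or a square adjacency matrix with
#'   dimnames. A non-symmetric matrix is symmetrized (by the maximum)
#'   with a warning.
#' @param inflation Inflation exponent > 1 (default 2).
#' @param maxIter Maximum expansion/inflation rounds (default 100).
#' @param tol Convergence tolerance on the max entry change
#'   (default 1e-6).
#' @param loopWeight Self-loop weight added to every node, on the scale
#'   of the largest edge weight (default 1).
#' @return A list of character vectors (sorted member ids), a partition
#'   of all nodes.
#' @export
mclCluster <- function(graph, inflation = 2, maxIter = 100L, tol = 1e-6,
                       loopWeight = 1) {
  stopifnot(inflation > 1)
  if (inherits(graph, "igraph")) {
    attr <- if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL
    A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = attr,
                                               sparse = TRUE))
  } else {
    A <- as.matrix(graph)
    if (is.null(rownames(A))) {
      rownames(A) <- colnames(A) <- paste0("n", seq_len(nrow(A)))
    }
  }
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-12))) {
    warning("non-symmetric input graph; symmetrizing by the maximum")
    A <- pmax(A, t(A))
  }
  n <- nrow(A)
  ids <- rownames(A)
  if (n == 1L) return(list(ids))
  ## loop weight is relative to the edge-weight scale, so clustering is
  ## invariant to uniform rescaling of all edge weights
  mx <- max(A)
  if (mx > 0) A <- A / mx
  diag(A) <- diag(A) + loopWeight
  M <- sweep(A, 2, colSums(A), "/")
  for (iter in seq_len(maxIter)) {
    prev <- M
    M <- M %*% M                        # expansion
    M <- M^inflation                    # inflation
    M[M < 1e-12] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tol) break
  }
  ## connected components of the converged flow's support
  supp <- (M > 1e-5) | (t(M) > 1e-5)
  diag(supp) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(supp[v, ] & comp == 0L))
    }
  }
  clusters <- split(ids, comp)
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[`, character(1), 1L))]
}
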