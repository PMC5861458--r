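# Independent brute-force oracles used across tests.

# connected components of the distance-threshold graph, by label propagation
# on the full pairwise distance matrix (no Delaunay, no igraph)
oracle_threshold_components <- function(pts, threshold) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  adj <- d <= threshold
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(labels[adj[i, ]])
      if (m < labels[i]) { labels[i] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# all-pairs shortest paths by Floyd-Warshall on an edge list (i, j, w)
oracle_floyd_warshall <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; w <- edges$length[k]
    D[i, j] <- min(D[i, j], w); D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# directed nearest-neighbor distances computed with plain loops
oracle_nn_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
  }, 0)
}
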