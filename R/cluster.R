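#' Segment localizations into clusters via an edge-thresholded Delaunay graph
#'
#' Builds the 2D Delaunay triangulation of the (x, y) projection, removes
#' all edges longer than `edge_threshold`, and labels the connected
#' components of the remaining graph as clusters. Because the Euclidean
#' minimum spanning tree is a subgraph of the Delaunay triangulation, these
#' components coincide with the components of the full distance-threshold
#' graph at the same cutoff, making the segmentation robust and cheap.
#' Components smaller than `min_size` are labeled noise (`NA`).
#'
#' @param table a [loc_table()] (denoised localizations of one channel).
#' @param edge_threshold maximum retained edge length in nm (default 30,
#'   the median of typical Delaunay edge-length distributions), or `"auto"`
#'   to use the median edge length of this dataset.
#' @param min_size minimum localizations per cluster (default 5); smaller
#'   components become noise.
#' @return object of class `cluster_set`: list with `table`, per-row integer
#'   `labels` (NA = noise), `edges` (data.frame i, j, length of retained
#'   Delaunay edges), `edge_threshold`, `min_size`.
#' @export
delaunay_segment <- function(table, edge_threshold = 30, min_size = 5) {
  n <- nrow(table)
  if (n < 3) {
    warning("fewer than 3 localizations; returning a single trivial cluster",
            call. = FALSE)
    labels <- if (n >= min_size) rep(1L, n) else rep(NA_integer_, n)
    return(.new_cluster_set(table, labels,
                            data.frame(i = integer(0), j = integer(0),
                                       length = numeric(0)),
                            edge_threshold, min_size))
  }
  x <- table$x; y <- table$y
  # deldir drops duplicated sites; map duplicates onto their representative
  key <- paste(x, y)
  rep_idx <- match(key, key)            # first occurrence per coordinate
  uniq <- which(rep_idx == seq_len(n))
  ux <- x[uniq]; uy <- y[uniq]
  edges <- .delaunay_edges(ux, uy)
  edges$i <- uniq[edges$i]; edges$j <- uniq[edges$j]
  if (identical(edge_threshold, "auto")) {
    edge_threshold <- stats::median(edges$length)
  }
  keep <- edges$length <= edge_threshold
  edges <- edges[keep, , drop = FALSE]
  # duplicates: zero-length edges to their representative
  dup <- which(rep_idx != seq_len(n))
  if (length(dup)) {
    edges <- rbind(edges, data.frame(i = dup, j = rep_idx[dup], length = 0))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  sizes <- table(comp)
  good <- as.integer(names(sizes)[sizes >= min_size])
  labels <- rep(NA_integer_, n)
  if (length(good)) {
    relabel <- stats::setNames(seq_along(good), good)
    inside <- comp %in% good
    labels[inside] <- as.integer(relabel[as.character(comp[inside])])
  }
  .new_cluster_set(table, labels, edges, edge_threshold, min_size)
}

.delaunay_edges <- function(x, y) {
  if (length(x) < 2) return(data.frame(i = integer(0), j = integer(0),
                                       length = numeric(0)))
  if (length(x) == 2) {
    return(data.frame(i = 1L, j = 2L,
                      length = sqrt(diff(x)^2 + diff(y)^2)))
  }
  pad <- pmax(c(diff(range(x)), diff(range(y))) * 0.1, 1)
  rw <- c(range(x) + c(-1, 1) * pad[1], range(y) + c(-1, 1) * pad[2])
  dd <- deldir::deldir(x, y, rw = rw)
  e <- dd$delsgs
  data.frame(i = pmin(e$ind1, e$ind2), j = pmax(e$ind1, e$ind2),
             length = sqrt((e$x1 - e$x2)^2 + (e$y1 - e$y2)^2))
}

.new_cluster_set <- function(table, labels, edges, edge_threshold, min_size) {
  structure(list(table = table, labels = labels, edges = edges,
                 edge_threshold = edge_threshold, min_size = min_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$labels)))
  cat(sprintf("<cluster_set> %d clusters from %d localizations (%d noise), edge threshold %.1f nm\n",
              k, length(x$labels), sum(is.na(x$labels)), x$edge_threshold))
  invisible(x)
}

#' @export
plot.cluster_set <- function(x, ...) {
  cols <- ifelse(is.na(x$labels), "grey80",
                 grDevices::hcl.colors(max(x$labels, na.rm = TRUE) + 1,
                                       "Dark 3")[x$labels])
  plot(x$table$x, x$table$y, col = cols, pch = 16, cex = 0.5, asp = 1,
       xlab = "x (nm)", ylab = "y (nm)", ...)
  invisible(x)
}

#' Cluster ids of a cluster set
#' @param cs a `cluster_set`.
#' @return sorted integer cluster ids (noise excluded).
#' @export
cluster_ids <- function(cs) sort(unique(stats::na.omit(cs$labels)))

# igraph of one cluster with Euclidean edge weights; vertices named by row index
.cluster_graph <- function(cs, id) {
  members <- which(cs$labels == id)
  e <- cs$edges[cs$edges$i %in% members & cs$edges$j %in% members, ,
                drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j, weight = e$length),
    directed = FALSE, vertices = data.frame(name = members))
  g
}

#' Extension (graph diameter) of clusters
#'
#' The extension of a cluster is the maximum over node pairs of the
#' shortest-path length (Euclidean edge weights) within the cluster's
#' thresholded Delaunay subgraph — a curve-following proxy for filament
#' length. The arg-max pair defines the two filament ends; ties are broken
#' by the lexicographically smallest pair of row indices.
#'
#' @param cs a `cluster_set` from [delaunay_segment()].
#' @param ids cluster ids to measure (default: all).
#' @return data.frame with `cluster`, `extension_nm`, `end1`, `end2` (row
#'   indices into `cs$table`); the extension path node sequence is attached
#'   as attribute `paths` (list keyed by cluster id).
#' @export
cluster_extension <- function(cs, ids = cluster_ids(cs)) {
  paths <- list()
  res <- lapply(ids, function(id) {
    members <- which(cs$labels == id)
    if (length(members) == 1) {
      paths[[as.character(id)]] <<- members
      return(data.frame(cluster = id, extension_nm = 0,
                        end1 = members, end2 = members))
    }
    g <- .cluster_graph(cs, id)
    d <- igraph::distances(g, weights = igraph::E(g)$weight)
    d[!is.finite(d)] <- -Inf   # defensive: disconnected pieces do not count
    m <- max(d)
    hits <- which(d == m, arr.ind = TRUE)
    nm <- as.integer(igraph::V(g)$name)
    pairs <- cbind(pmin(nm[hits[, 1]], nm[hits[, 2]]),
                   pmax(nm[hits[, 1]], nm[hits[, 2]]))
    best <- order(pairs[, 1], pairs[, 2])[1]
    e1 <- pairs[best, 1]; e2 <- pairs[best, 2]
    sp <- igraph::shortest_paths(g, from = as.character(e1),
                                 to = as.character(e2),
                                 weights = igraph::E(g)$weight)$vpath[[1]]
    paths[[as.character(id)]] <<- as.integer(names(sp))
    data.frame(cluster = id, extension_nm = m, end1 = e1, end2 = e2)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cluster = integer(0), extension_nm = numeric(0),
               end1 = integer(0), end2 = integer(0))
  attr(out, "paths") <- paths
  out
}

#' Calibration profile from isolated-antibody localization counts
#'
#' Summarizes the number of localizations produced by single isolated
#' labeled antibodies imaged under the same conditions; used to convert
#' cluster localization counts into molecule counts.
#'
#' @param counts vector of per-antibody localization counts.
#' @param stat summary used for molecule counting: `"mean"` (the expected
#'   number of localizations per antibody; default) or `"median"`.
#' @return object of class `calibration_profile` with the counts and both
#'   summaries.
#' @export
calibration_profile <- function(counts, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  counts <- as.numeric(counts)
  if (!length(counts) || any(counts <= 0)) {
    stop("calibration counts must be positive", call. = FALSE)
  }
  structure(list(counts = counts, mean = mean(counts),
                 median = stats::median(counts), stat = stat),
            class = "calibration_profile")
}

.calibration_value <- function(calibration) {
  if (is.numeric(calibration)) return(as.numeric(calibration))
  if (inherits(calibration, "calibration_profile")) {
    return(calibration[[calibration$stat]])
  }
  stop("missing or invalid calibration; supply calibration_profile() or a number",
       call. = FALSE)
}

#' Estimate molecule counts per cluster
#'
#' Divides the number of localizations in each cluster by the expected
#' number of localizations per isolated labeled antibody. Rounding is
#' half-away-from-zero; the raw quotient is retained for statistics.
#'
#' @param cs a `cluster_set`.
#' @param calibration a [calibration_profile()] or a positive number
#'   (localizations per antibody).
#' @param ids cluster ids (default all).
#' @return data.frame with `cluster`, `n_locs`, `molecules_raw`, `molecules`.
#' @export
estimate_molecules <- function(cs, calibration, ids = cluster_ids(cs)) {
  div <- .calibration_value(calibration)
  if (!is.finite(div) || div <= 0) {
    stop("calibration value must be > 0", call. = FALSE)
  }
  n_locs <- vapply(ids, function(id) sum(cs$labels == id, na.rm = TRUE), 0L)
  raw <- n_locs / div
  data.frame(cluster = ids, n_locs = n_locs, molecules_raw = raw,
             molecules = floor(raw + 0.5))
}
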