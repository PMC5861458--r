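#' Photon-weighted cluster centroids
#'
#' @param cs a `cluster_set`.
#' @param ids cluster ids (default all).
#' @return data.frame with `cluster`, `x`, `y` (photon-weighted means of the
#'   member localizations). If all member photon counts are zero the
#'   unweighted mean is used with a warning.
#' @export
weighted_centroid <- function(cs, ids = cluster_ids(cs)) {
  res <- lapply(ids, function(id) {
    m <- which(cs$labels == id)
    w <- cs$table$photons[m]
    if (sum(w) <= 0) {
      warning("cluster ", id, " has zero total photons; using unweighted mean",
              call. = FALSE)
      w <- rep(1, length(m))
    }
    data.frame(cluster = id,
               x = sum(w * cs$table$x[m]) / sum(w),
               y = sum(w * cs$table$y[m]) / sum(w))
  })
  if (!length(res)) return(data.frame(cluster = integer(0), x = numeric(0),
                                      y = numeric(0)))
  do.call(rbind, res)
}

# nearest-neighbor distances from each row of `a` to the point set `b` (2D)
.nn_dist <- function(a, b) {
  if (!nrow(b)) return(rep(NA_real_, nrow(a)))
  FNN::get.knnx(b, a, k = 1)$nn.dist[, 1]
}

#' Cross-channel cluster pairing and proximity metrics
#'
#' Every query cluster is matched to the partner-channel cluster with the
#' nearest photon-weighted centroid (ties broken by the lower partner id).
#' Three proximity measures are reported: C2C (centroid-to-centroid), P2P
#' (median over query localizations of the distance to the nearest
#' localization of the matched partner cluster) and E2P (minimum over the
#' two filament ends of the distance to the matched partner cluster's
#' nearest localization). A pair is called colocalized when
#' `c2c < c2c_threshold`.
#'
#' @param query,partner `cluster_set`s of the two channels, registered into
#'   one coordinate frame.
#' @param c2c_threshold colocalization threshold on C2C in nm (default 200
#'   for protein-protein pairs; 100 is the convention for BrdU-RPA).
#' @param both_directions also report the partner-to-query P2P
#'   (`p2p_ba_nm`), since the point-to-point definition is directional.
#' @return `pair_metrics` data.frame: one row per query cluster with
#'   `cluster`, `partner`, `c2c_nm`, `p2p_nm`, `e2p_nm`, `colocalized`.
#'   With an empty partner set all distances are NA and flags FALSE.
#' @export
pair_clusters <- function(query, partner, c2c_threshold = 200,
                          both_directions = FALSE) {
  qc <- weighted_centroid(query)
  pc <- weighted_centroid(partner)
  if (!nrow(qc)) {
    out <- data.frame(cluster = integer(0), partner = integer(0),
                      c2c_nm = numeric(0), p2p_nm = numeric(0),
                      e2p_nm = numeric(0), colocalized = logical(0))
    class(out) <- c("pair_metrics", "data.frame")
    return(out)
  }
  ext <- cluster_extension(query)
  rows <- lapply(seq_len(nrow(qc)), function(k) {
    if (!nrow(pc)) {
      return(data.frame(cluster = qc$cluster[k], partner = NA_integer_,
                        c2c_nm = NA_real_, p2p_nm = NA_real_,
                        e2p_nm = NA_real_, colocalized = FALSE))
    }
    d <- sqrt((pc$x - qc$x[k])^2 + (pc$y - qc$y[k])^2)
    best <- which(d == min(d))
    best <- best[which.min(pc$cluster[best])]
    pid <- pc$cluster[best]
    pm <- which(partner$labels == pid)
    ppts <- cbind(partner$table$x[pm], partner$table$y[pm])
    qm <- which(query$labels == qc$cluster[k])
    qpts <- cbind(query$table$x[qm], query$table$y[qm])
    p2p <- stats::median(.nn_dist(qpts, ppts))
    er <- ext[ext$cluster == qc$cluster[k], ]
    epts <- cbind(query$table$x[c(er$end1, er$end2)],
                  query$table$y[c(er$end1, er$end2)])
    e2p <- min(.nn_dist(epts, ppts))
    out <- data.frame(cluster = qc$cluster[k], partner = pid,
                      c2c_nm = d[best], p2p_nm = p2p, e2p_nm = e2p,
                      colocalized = d[best] < c2c_threshold)
    if (both_directions) out$p2p_ba_nm <- stats::median(.nn_dist(ppts, qpts))
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pair_metrics", "data.frame")
  out
}

#' Per-cell colocalization fraction
#'
#' Fraction of query clusters whose nearest partner centroid lies within
#' the C2C threshold, computed per cell.
#'
#' @param metrics a `pair_metrics` data.frame (or an rbind of several).
#' @param cell a grouping vector (one value per row of `metrics`); defaults
#'   to a single cell.
#' @return data.frame with `cell`, `n_clusters`, `fraction` in [0, 1].
#'   Cells with no query clusters are skipped with a warning.
#' @export
coloc_fraction <- function(metrics, cell = rep("cell1", nrow(metrics))) {
  if (!nrow(metrics)) {
    warning("no query clusters; nothing to summarize", call. = FALSE)
    return(data.frame(cell = character(0), n_clusters = integer(0),
                      fraction = numeric(0)))
  }
  parts <- split(metrics$colocalized, cell)
  data.frame(cell = names(parts),
             n_clusters = vapply(parts, length, 0L),
             fraction = vapply(parts, mean, 0),
             row.names = NULL)
}
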