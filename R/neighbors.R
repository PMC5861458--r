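# grid-binned fixed-radius neighbor counting; O(n) cells, closed balls
.count_within <- function(query, ref, radius, exclude_self = FALSE) {
  nq <- nrow(query)
  if (nq == 0) return(integer(0))
  if (nrow(ref) == 0) return(integer(nq))
  h <- radius
  key <- function(p) {
    i <- floor(p[, 1] / h); j <- floor(p[, 2] / h); k <- floor(p[, 3] / h)
    paste(i, j, k)
  }
  rkey <- key(ref)
  bins <- split(seq_len(nrow(ref)), rkey)
  qi <- floor(query[, 1] / h); qj <- floor(query[, 2] / h)
  qk <- floor(query[, 3] / h)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  counts <- integer(nq)
  r2 <- radius^2 * (1 + 1e-12)  # closed ball, robust to FP noise at the rim
  for (q in seq_len(nq)) {
    cand <- integer(0)
    for (o in seq_len(nrow(off))) {
      b <- bins[[paste(qi[q] + off$di[o], qj[q] + off$dj[o], qk[q] + off$dk[o])]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    if (!length(cand)) next
    dx <- ref[cand, 1] - query[q, 1]
    dy <- ref[cand, 2] - query[q, 2]
    dz <- ref[cand, 3] - query[q, 3]
    n <- sum(dx * dx + dy * dy + dz * dz <= r2)
    if (exclude_self) n <- n - 1L
    counts[q] <- n
  }
  counts
}

.xyz <- function(table) cbind(table$x, table$y, table$z)

#' Neighbor-count denoising across two registered channels
#'
#' A localization is kept iff it has at least `min_same` same-channel
#' neighbors or at least `min_cross` other-channel neighbors within
#' `radius` (closed ball, 3D; the localization itself is excluded from its
#' own count). The default thresholds mirror the expected number of
#' detections produced by a single isolated labeled antibody, so isolated
#' non-specific detections are rejected while structure-bound ones survive.
#'
#' @param table_a,table_b [loc_table()]s for the two channels, already
#'   registered into one coordinate frame. `table_b` may be `NULL` for
#'   single-channel data (cross counts are then zero).
#' @param radius neighborhood radius in nm (default 100). `"auto"`
#'   recomputes mean + 3 SD of the first-nearest-neighbor distances of the
#'   combined dataset.
#' @param min_same,min_cross neighbor-count thresholds (defaults 30 and 10).
#' @return list with `denoise_mask` data.frames `mask_a` and `mask_b`
#'   (reason code `"neighbor"` for rejections) and the `radius` used.
#' @export
neighbor_filter <- function(table_a, table_b = NULL, radius = 100,
                            min_same = 30, min_cross = 10) {
  pa <- .xyz(table_a)
  pb <- if (is.null(table_b)) matrix(numeric(0), 0, 3) else .xyz(table_b)
  if (identical(radius, "auto")) {
    radius <- .auto_radius(rbind(pa, pb))
  }
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  mask_of <- function(same, cross) {
    keep <- same >= min_same | cross >= min_cross
    m <- data.frame(keep = keep,
                    reason = ifelse(keep, "kept", "neighbor"),
                    n_same = same, n_cross = cross,
                    stringsAsFactors = FALSE)
    class(m) <- c("denoise_mask", "data.frame")
    m
  }
  same_a <- .count_within(pa, pa, radius, exclude_self = TRUE)
  cross_a <- .count_within(pa, pb, radius)
  out <- list(mask_a = mask_of(same_a, cross_a), radius = radius)
  if (!is.null(table_b)) {
    same_b <- .count_within(pb, pb, radius, exclude_self = TRUE)
    cross_b <- .count_within(pb, pa, radius)
    out$mask_b <- mask_of(same_b, cross_b)
  }
  out
}

# radius rule: mean + 3 SD of first-nearest-neighbor distances
.auto_radius <- function(pts) {
  n <- nrow(pts)
  if (n < 2) stop("auto radius needs at least 2 points", call. = FALSE)
  nn <- FNN::get.knn(pts, k = 1)$nn.dist[, 1]
  mean(nn) + 3 * stats::sd(nn)
}
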