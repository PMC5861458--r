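#' Voronoi tessellation annotation of a localization table
#'
#' Computes, for every localization, the volume (3D) or area (2D) of its
#' Voronoi cell. Cell size is inversely related to local density, which is
#' what the downstream [voronoi_filter()] exploits: sparse background
#' localizations sit in large cells, clustered signal in small ones.
#' Cells adjacent to the convex hull of the acquisition volume are unbounded;
#' they are flagged and treated as infinitely large.
#'
#' The 3D tessellation is delegated to Python's scipy.spatial (bundled
#' helper script); the 2D tessellation uses deldir, with cells clipped by
#' the enclosing window counted as unbounded.
#'
#' @param table a [loc_table()] (or data.frame with x, y, z columns).
#' @param dim 3 (default) for volumes from (x, y, z), 2 for areas from (x, y).
#' @return object of class `voronoi_annotation`: data.frame with columns
#'   `volume` (nm^3, or nm^2 when `dim = 2`) and `bounded`.
#' @export
voronoi_annotate <- function(table, dim = 3) {
  pts <- cbind(table$x, table$y, if (dim == 3) table$z)
  if (nrow(pts) < 5) stop("need at least 5 localizations", call. = FALSE)
  if (dim == 3) {
    rng <- apply(pts, 2, function(v) diff(range(v)))
    if (any(rng <= .Machine$double.eps)) {
      stop("points are coplanar/degenerate in 3D; use the 2D fallback, voronoi_annotate(dim = 2)",
           call. = FALSE)
    }
    ann <- .voronoi3d_scipy(pts)
  } else {
    ann <- .voronoi2d_deldir(pts)
  }
  structure(ann, class = c("voronoi_annotation", "data.frame"))
}

.voronoi3d_scipy <- function(pts) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") {
    stop("no python interpreter on PATH; 3D Voronoi volumes need scipy",
         call. = FALSE)
  }
  script <- system.file("python", "voronoi_cells.py", package = "stormfoci")
  inp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(inp, out)), add = TRUE)
  utils::write.table(pts, inp, sep = ",", row.names = FALSE, col.names = FALSE)
  status <- system2(py, c(script, inp, out), stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) {
    msg <- paste(status, collapse = "\n")
    if (grepl("QhullError|coplanar|degenerate", msg, ignore.case = TRUE)) {
      stop("degenerate 3D input for Voronoi tessellation; consider dim = 2.\n",
           msg, call. = FALSE)
    }
    stop("3D Voronoi computation failed:\n", msg, call. = FALSE)
  }
  res <- utils::read.csv(out)
  vol <- as.numeric(res$volume)
  vol[res$bounded != 1] <- Inf
  data.frame(volume = vol, bounded = res$bounded == 1)
}

.voronoi2d_deldir <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  pad <- pmax(c(diff(range(x)), diff(range(y))) * 0.1, 1)
  rw <- c(range(x) + c(-1, 1) * pad[1], range(y) + c(-1, 1) * pad[2])
  dd <- deldir::deldir(x, y, rw = rw)
  ti <- deldir::tile.list(dd)
  vol <- rep(NA_real_, length(x))
  bounded <- rep(FALSE, length(x))
  for (tl in ti) {
    i <- tl$ptNum
    on_window <- any(tl$bp)  # vertex on the enclosing window => clipped cell
    vol[i] <- if (on_window) Inf else tl$area
    bounded[i] <- !on_window
  }
  vol[is.na(vol)] <- Inf  # duplicated seeds get no tile from deldir
  data.frame(volume = vol, bounded = bounded)
}

#' Density filter on Voronoi cell sizes
#'
#' Keeps a localization iff its Voronoi cell is bounded and no larger than
#' the threshold. The automatic threshold is the median of the bounded cell
#' sizes in the dataset, following the rule that cells larger than the
#' dataset median are background. A manual threshold is accepted but a
#' warning is raised when it falls outside the interval spanned by the mean
#' and the median of the bounded cell-size distribution, the recommended
#' operating band.
#'
#' @param annotation a `voronoi_annotation` from [voronoi_annotate()].
#' @param threshold `"auto"` (median rule) or a numeric cell-size cutoff in
#'   the units of the annotation (nm^3 for 3D).
#' @return object of class `denoise_mask`: data.frame with logical `keep`
#'   and a `reason` code (`"kept"` or `"voronoi"`), plus the threshold used
#'   as attribute `threshold`.
#' @export
voronoi_filter <- function(annotation, threshold = "auto") {
  vols <- annotation$volume
  bvols <- vols[annotation$bounded]
  med <- stats::median(bvols)
  mea <- mean(bvols)
  if (identical(threshold, "auto")) {
    thr <- med
  } else {
    thr <- as.numeric(threshold)
    lo <- min(mea, med); hi <- max(mea, med)
    if (thr < lo || thr > hi) {
      warning(sprintf(
        "manual Voronoi threshold %.3g lies outside the mean/median band [%.3g, %.3g]",
        thr, lo, hi), call. = FALSE)
    }
  }
  keep <- annotation$bounded & vols <= thr
  mask <- data.frame(keep = keep,
                     reason = ifelse(keep, "kept", "voronoi"),
                     stringsAsFactors = FALSE)
  attr(mask, "threshold") <- thr
  class(mask) <- c("denoise_mask", "data.frame")
  mask
}
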