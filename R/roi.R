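#' Nucleus region of interest (closed polygon)
#'
#' @param x,y polygon vertex coordinates in nm (not repeated at the end;
#'   the polygon is closed implicitly). Must be simple (non
#'   self-intersecting) with positive area.
#' @return object of class `nucleus_roi` with `x`, `y`, `area` (nm^2).
#' @export
nucleus_roi <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  a <- .shoelace(x, y)
  if (abs(a) <= 0) stop("polygon has zero area", call. = FALSE)
  structure(list(x = x, y = y, area = abs(a)), class = "nucleus_roi")
}

.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Rectangular ROI helper
#' @param width,height rectangle size in nm.
#' @param center rectangle center, c(x, y).
#' @return a [nucleus_roi()].
#' @export
roi_rect <- function(width, height = width, center = c(0, 0)) {
  nucleus_roi(center[1] + c(-1, 1, 1, -1) * width / 2,
              center[2] + c(-1, -1, 1, 1) * height / 2)
}

#' Circular (polygonal) ROI helper
#' @param radius circle radius in nm.
#' @param center circle center, c(x, y).
#' @param n_vertices polygon resolution.
#' @return a [nucleus_roi()].
#' @export
roi_circle <- function(radius, center = c(0, 0), n_vertices = 64) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  nucleus_roi(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Read an ROI polygon from a CSV of vertices (columns x_nm, y_nm)
#' @param path CSV file path.
#' @return a [nucleus_roi()].
#' @export
read_roi <- function(path) {
  v <- utils::read.csv(path)
  nucleus_roi(v$x_nm, v$y_nm)
}

#' Point-in-ROI test
#' @param roi a [nucleus_roi()].
#' @param x,y point coordinates (vectorized).
#' @return logical vector; boundary points count as inside.
#' @export
roi_contains <- function(roi, x, y) {
  sp::point.in.polygon(x, y, roi$x, roi$y) > 0
}

#' Sample points uniformly inside an ROI (rejection sampling from the
#' bounding box)
#' @param roi a [nucleus_roi()].
#' @param n number of points.
#' @return n x 2 matrix of coordinates.
#' @export
roi_sample <- function(roi, n) {
  bx <- range(roi$x); by <- range(roi$y)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 1.5 * diff(bx) * diff(by) / roi$area) + 10
    cand <- cbind(stats::runif(m, bx[1], bx[2]), stats::runif(m, by[1], by[2]))
    ok <- roi_contains(roi, cand[, 1], cand[, 2])
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
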