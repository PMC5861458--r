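#' Fiducial marker set for two-channel registration
#'
#' @param a,b matrices (n x 3) of fiducial positions in channels A and B;
#'   rows correspond (index i in `a` is the same bead as index i in `b`).
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) == 2) a <- cbind(a, 0)
  if (ncol(b) == 2) b <- cbind(b, 0)
  if (nrow(a) != nrow(b)) {
    stop("fiducial channels have mismatched counts (", nrow(a), " vs ",
         nrow(b), ")", call. = FALSE)
  }
  if (nrow(a) < 1) stop("at least one fiducial pair is required", call. = FALSE)
  structure(list(a = a, b = b), class = "fiducial_set")
}

#' Estimate the rigid shift registering channel B onto channel A
#'
#' Translation minimizing the sum of squared 3D Euclidean distances between
#' matched fiducials, i.e. the mean per-pair displacement `a - b`. Applying
#' the returned shift to channel B aligns it with channel A.
#'
#' @param fiducials a [fiducial_set()].
#' @return list with `dx`, `dy`, `dz` (nm) and the residual RMS distance
#'   after registration.
#' @export
register_channels <- function(fiducials) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  d <- fiducials$a - fiducials$b
  shift <- colMeans(d)
  resid <- sweep(d, 2, shift)
  list(dx = shift[1], dy = shift[2], dz = shift[3],
       rms = sqrt(mean(rowSums(resid^2))))
}

#' Apply a rigid shift to a localization table
#'
#' @param table a [loc_table()].
#' @param shift list with `dx`, `dy`, `dz` as from [register_channels()].
#' @return shifted table.
#' @export
apply_shift <- function(table, shift) {
  table$x <- table$x + shift$dx
  table$y <- table$y + shift$dy
  table$z <- table$z + shift$dz
  table
}
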