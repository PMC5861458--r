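#' Thompson localization precision
#'
#' Per-axis localization variance for a fitted emitter, following the
#' Thompson-Larson-Webb formula:
#' \deqn{\sigma^2 = s^2/N + a^2/(12N) + 8\pi s^4 b^2 / (a^2 N^2)}
#' with `s` the PSF standard deviation, `N` the photon count, `a` the pixel
#' size and `b` the background noise (photons per pixel). The combined
#' lateral precision is \eqn{\sigma = \sqrt{\sigma_x^2 + \sigma_y^2}}.
#'
#' @param photons photon count(s), > 0. Vectorized.
#' @param psf_sigma PSF standard deviation in nm.
#' @param pixel camera pixel size in nm.
#' @param background background photons per pixel, >= 0.
#' @return list with `sigma_x`, `sigma_y` (identical for a symmetric PSF)
#'   and combined `sigma`, all in nm.
#' @export
thompson_precision <- function(photons, psf_sigma = 150, pixel = 160,
                               background = 0) {
  if (any(photons <= 0)) stop("photons must be > 0", call. = FALSE)
  if (psf_sigma <= 0 || pixel <= 0) stop("psf_sigma and pixel must be > 0",
                                         call. = FALSE)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  s <- psf_sigma; N <- photons; a <- pixel; b <- background
  var_axis <- s^2 / N + a^2 / (12 * N) + 8 * pi * s^4 * b^2 / (a^2 * N^2)
  sx <- sqrt(var_axis)
  list(sigma_x = sx, sigma_y = sx, sigma = sqrt(2 * var_axis))
}

#' Annotate a localization table with Thompson precision
#'
#' Fills `sigma_x`, `sigma_y` and combined `sigma` columns from per-row
#' photon counts.
#'
#' @inheritParams thompson_precision
#' @param table a [loc_table()].
#' @return the table with precision columns populated.
#' @export
add_precision <- function(table, psf_sigma = 150, pixel = 160, background = 0) {
  p <- thompson_precision(table$photons, psf_sigma, pixel, background)
  table$sigma_x <- p$sigma_x
  table$sigma_y <- p$sigma_y
  table$sigma <- p$sigma
  table
}

#' Photon and precision quality filter
#'
#' Discards localizations with fewer than `min_photons` detected photons or
#' a combined lateral precision worse (numerically larger) than `max_sigma`.
#' Note the filter keeps *good* localizations: small sigma means high
#' precision.
#'
#' @param table a [loc_table()] with `photons` and `sigma` populated.
#' @param min_photons minimum photon count retained (default 1000).
#' @param max_sigma worst combined precision retained, nm (default 15).
#' @return filtered table; the number of removed rows is attached as
#'   attribute `n_rejected`.
#' @export
filter_quality <- function(table, min_photons = 1000, max_sigma = 15) {
  if (!"sigma" %in% names(table)) {
    stop("table has no 'sigma' column; run thompson_precision()/add_precision() first",
         call. = FALSE)
  }
  keep <- table$photons >= min_photons & table$sigma <= max_sigma
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Merge repeated blinking detections across consecutive frames
#'
#' A fluorophore that stays on across camera frames yields one localization
#' per frame. Chains of same-channel localizations, each within
#' `link_radius` of the chain's running photon-weighted position and within
#' `max_gap_frames` frames of the chain's last member, are merged into one
#' record carrying the photon-weighted mean position, the summed photon
#' count and the first frame of the chain.
#'
#' @param table a [loc_table()].
#' @param max_gap_frames maximum frame separation inside a chain (default 10).
#' @param link_radius gating radius in nm around the chain's running
#'   photon-weighted centroid (default 50).
#' @return merged [loc_table()] with an `n_merged` column counting the
#'   localizations absorbed into each record.
#' @export
link_frames <- function(table, max_gap_frames = 10, link_radius = 50) {
  if (link_radius <= 0) stop("link_radius must be > 0", call. = FALSE)
  if (nrow(table) == 0) {
    table$n_merged <- integer(0)
    return(table)
  }
  ord <- order(table$channel, table$frame)
  tb <- table[ord, , drop = FALSE]
  n <- nrow(tb)
  assign_id <- integer(n)
  # open chains, per channel: running weighted sums and last frame
  res <- list()
  for (ch in unique(tb$channel)) {
    idx <- which(tb$channel == ch)
    cx <- cy <- cz <- cw <- numeric(0)  # photon-weighted sums and weights
    clast <- cfirst <- numeric(0)
    cid <- integer(0)
    next_id <- 1L
    for (i in idx) {
      open <- which(tb$frame[i] - clast <= max_gap_frames &
                    tb$frame[i] > clast)
      hit <- 0L
      if (length(open)) {
        dx <- cx[open] / cw[open] - tb$x[i]
        dy <- cy[open] / cw[open] - tb$y[i]
        dz <- cz[open] / cw[open] - tb$z[i]
        d2 <- dx * dx + dy * dy + dz * dz
        j <- which.min(d2)
        if (d2[j] <= link_radius^2) hit <- open[j]
      }
      w <- max(tb$photons[i], .Machine$double.eps)
      if (hit > 0L) {
        cx[hit] <- cx[hit] + w * tb$x[i]
        cy[hit] <- cy[hit] + w * tb$y[i]
        cz[hit] <- cz[hit] + w * tb$z[i]
        cw[hit] <- cw[hit] + w
        clast[hit] <- tb$frame[i]
        assign_id[i] <- cid[hit]
      } else {
        cx <- c(cx, w * tb$x[i]); cy <- c(cy, w * tb$y[i])
        cz <- c(cz, w * tb$z[i]); cw <- c(cw, w)
        clast <- c(clast, tb$frame[i]); cfirst <- c(cfirst, tb$frame[i])
        cid <- c(cid, next_id)
        assign_id[i] <- next_id
        next_id <- next_id + 1L
      }
      # retire chains that can no longer accept members (keeps `open` small)
      dead <- clast < tb$frame[i] - max_gap_frames
      if (any(dead)) {
        keep <- !dead
        cx <- cx[keep]; cy <- cy[keep]; cz <- cz[keep]; cw <- cw[keep]
        clast <- clast[keep]; cfirst <- cfirst[keep]; cid <- cid[keep]
      }
    }
    res[[ch]] <- data.frame(channel = ch, id = assign_id[idx],
                            x = tb$x[idx], y = tb$y[idx], z = tb$z[idx],
                            photons = tb$photons[idx], frame = tb$frame[idx])
  }
  merged <- do.call(rbind, lapply(res, function(df) {
    agg <- lapply(split(df, df$id), function(g) {
      w <- pmax(g$photons, .Machine$double.eps)
      data.frame(x = sum(w * g$x) / sum(w), y = sum(w * g$y) / sum(w),
                 z = sum(w * g$z) / sum(w), photons = sum(g$photons),
                 frame = min(g$frame), channel = g$channel[1],
                 n_merged = nrow(g))
    })
    do.call(rbind, agg)
  }))
  rownames(merged) <- NULL
  merged <- merged[order(merged$channel, merged$frame), , drop = FALSE]
  rownames(merged) <- NULL
  loc_table(merged, pixel_nm = attr(table, "pixel_nm"),
            dialect = attr(table, "dialect"))
}
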