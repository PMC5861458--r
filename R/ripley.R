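#' Bivariate Ripley's K between two point sets inside an ROI
#'
#' \deqn{K_{12}(r) = \frac{A}{n_A n_B} \sum_i \sum_j 1[d(a_i, b_j) \le r]}
#' with A the ROI area. Under independent complete spatial randomness of
#' both channels, \eqn{E K_{12}(r) = \pi r^2}. No analytic edge correction
#' is applied: the same uncorrected estimator is used for the observed and
#' the randomized data in [ripley_envelope()], so boundary bias cancels in
#' the envelope comparison.
#'
#' @param a,b n x 2 matrices (or data.frames with x, y) of points, e.g.
#'   cluster centroids, all inside `roi`.
#' @param radii radius grid in nm (default 0 to 500 by 10).
#' @param roi a [nucleus_roi()].
#' @return numeric vector K12(r), same length as `radii` (non-decreasing).
#' @export
ripley_bivariate <- function(a, b, radii = seq(0, 500, by = 10), roi) {
  a <- .as_xy(a); b <- .as_xy(b)
  if (!nrow(a) || !nrow(b)) stop("both channels must be non-empty",
                                 call. = FALSE)
  d <- sort(sqrt(outer(a[, 1], b[, 1], "-")^2 +
                   outer(a[, 2], b[, 2], "-")^2))
  counts <- findInterval(radii, d)  # pairs with distance <= r (ties included)
  roi$area / (nrow(a) * nrow(b)) * counts
}

.as_xy <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  p[, 1:2, drop = FALSE]
}

#' Monte-Carlo randomization envelope for bivariate Ripley's K
#'
#' Re-draws the channel-A centroids uniformly inside the nucleus ROI
#' (channel B fixed) `n_rand` times, recomputes K12 each time, and forms the
#' pointwise 2.5/97.5 percentile envelope. An observed curve above, below,
#' or within the envelope indicates clustering, exclusion, or independence
#' of the two channels. Set `randomize = "both"` to re-draw both channels.
#'
#' @inheritParams ripley_bivariate
#' @param n_rand number of randomizations (default 100, >= 2).
#' @param seed RNG seed for reproducible envelopes.
#' @param randomize `"a"` (default, matching randomization of the query
#'   channel's cluster positions) or `"both"`.
#' @return object of class `ripley_envelope` with `radii`, `observed`,
#'   `env_mean`, `env_lo`, `env_hi`, `n_rand`, `seed` and a per-radius and
#'   overall `classification` (clustering / exclusion / independent).
#' @export
ripley_envelope <- function(a, b, radii = seq(0, 500, by = 10), roi,
                            n_rand = 100, seed = NULL,
                            randomize = c("a", "both")) {
  randomize <- match.arg(randomize)
  if (n_rand < 2) stop("n_rand must be >= 2", call. = FALSE)
  a <- .as_xy(a); b <- .as_xy(b)
  if (!is.null(seed)) set.seed(seed)
  obs <- ripley_bivariate(a, b, radii, roi)
  sims <- matrix(NA_real_, n_rand, length(radii))
  for (s in seq_len(n_rand)) {
    ra <- roi_sample(roi, nrow(a))
    rb <- if (randomize == "both") roi_sample(roi, nrow(b)) else b
    sims[s, ] <- ripley_bivariate(ra, rb, radii, roi)
  }
  lo <- apply(sims, 2, stats::quantile, probs = 0.025)
  hi <- apply(sims, 2, stats::quantile, probs = 0.975)
  mean_k <- colMeans(sims)
  cls <- rep("independent", length(radii))
  cls[obs > hi] <- "clustering"
  cls[obs < lo] <- "exclusion"
  overall <- if (any(cls == "clustering")) "clustering"
             else if (any(cls == "exclusion")) "exclusion" else "independent"
  structure(list(radii = radii, observed = obs, env_mean = mean_k,
                 env_lo = lo, env_hi = hi, n_rand = n_rand, seed = seed,
                 per_radius = cls, classification = overall),
            class = "ripley_envelope")
}

#' @export
print.ripley_envelope <- function(x, ...) {
  cat(sprintf("<ripley_envelope> %d radii (%.0f-%.0f nm), %d randomizations\n",
              length(x$radii), min(x$radii), max(x$radii), x$n_rand))
  cat("  classification:", x$classification, "\n")
  cat(sprintf("  radii inside envelope: %.0f%%\n",
              100 * mean(x$per_radius == "independent")))
  invisible(x)
}

#' @export
plot.ripley_envelope <- function(x, ...) {
  ylim <- range(c(x$observed, x$env_lo, x$env_hi))
  plot(x$radii, x$observed, type = "l", lwd = 2, col = "purple",
       xlab = "r (nm)", ylab = expression(K[12](r)), ylim = ylim, ...)
  graphics::polygon(c(x$radii, rev(x$radii)), c(x$env_lo, rev(x$env_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$radii, x$env_mean, col = "steelblue")
  graphics::lines(x$radii, x$observed, lwd = 2, col = "purple")
  invisible(x)
}

#' Tabulate a Ripley envelope as a data.frame
#' @param x a `ripley_envelope`.
#' @param ... unused.
#' @return data.frame with r, K_obs, env_mean, env_lo, env_hi.
#' @export
as.data.frame.ripley_envelope <- function(x, ...) {
  data.frame(r = x$radii, K_obs = x$observed, env_mean = x$env_mean,
             env_lo = x$env_lo, env_hi = x$env_hi)
}
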