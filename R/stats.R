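#' Simultaneous multi-group comparison with a max-t adjustment
#'
#' All pairwise Welch-type t statistics (heteroscedasticity-robust
#' variances, no pooling) are computed on optionally log-transformed data.
#' Familywise-adjusted two-sided p-values come from a seeded parametric
#' bootstrap of the joint null distribution of the maximum |t|: group means
#' are drawn as independent normals with the plug-in standard errors and
#' group variances as scaled chi-squares with the observed degrees of
#' freedom, preserving the correlation between statistics that share a
#' group. This is a Tukey-Kramer-style single-step adjustment designed for
#' unbalanced, non-normal, heteroscedastic data. Adjusted p-values are
#' floored at the raw Welch p-value, so the adjustment can only inflate.
#'
#' @param values numeric observations.
#' @param groups group labels (same length as `values`); every group needs
#'   n >= 3.
#' @param log_transform log-transform first (default TRUE); zeros are
#'   shifted by half the smallest positive observation before logging.
#' @param n_draws Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param seed RNG seed.
#' @return object of class `maxt_compare`: data.frame of pairwise
#'   comparisons with `group1`, `group2`, `estimate` (difference of means on
#'   the analysis scale), `t`, `df` (Welch-Satterthwaite), `p_raw`, `p_adj`.
#' @export
maxt_compare <- function(values, groups, log_transform = TRUE,
                         n_draws = 1e5, seed = NULL) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    stop("group(s) with fewer than 3 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  shift <- 0
  if (log_transform) {
    if (any(values < 0)) stop("log transform requires non-negative values",
                              call. = FALSE)
    if (any(values == 0)) shift <- min(values[values > 0]) / 2
    values <- log(values + shift)
  }
  gl <- sort(unique(groups))
  G <- length(gl)
  m <- vapply(gl, function(g) mean(values[groups == g]), 0)
  v <- vapply(gl, function(g) stats::var(values[groups == g]), 0)
  n <- as.numeric(sizes[gl])
  se2 <- v / n
  pairs <- utils::combn(G, 2)
  tt <- dfree <- est <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    est[p] <- m[i] - m[j]
    denom <- se2[i] + se2[j]
    tt[p] <- if (denom > 0) est[p] / sqrt(denom) else 0
    dfree[p] <- if (denom > 0) {
      denom^2 / (se2[i]^2 / (n[i] - 1) + se2[j]^2 / (n[j] - 1))
    } else Inf
  }
  p_raw <- 2 * stats::pt(-abs(tt), dfree)
  p_raw[!is.finite(tt) | tt == 0] <- pmin(p_raw[!is.finite(tt) | tt == 0], 1)
  # parametric bootstrap of max |t| under the complete null
  if (!is.null(seed)) set.seed(seed)
  zm <- matrix(stats::rnorm(n_draws * G), n_draws, G)
  zm <- sweep(zm, 2, sqrt(se2), "*")            # simulated group means
  vv <- matrix(stats::rchisq(n_draws * G, rep(n - 1, each = n_draws)),
               n_draws, G)
  vv <- sweep(vv, 2, n - 1, "/")                # chi2_{n-1}/(n-1) factors
  vv <- sweep(vv, 2, se2, "*")                  # simulated se^2
  maxt <- rep(0, n_draws)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    denom <- vv[, i] + vv[, j]
    tstar <- abs(zm[, i] - zm[, j]) / sqrt(denom)
    tstar[denom <= 0] <- 0
    maxt <- pmax(maxt, tstar)
  }
  p_adj <- vapply(abs(tt), function(t0) mean(maxt >= t0), 0)
  p_adj <- pmin(1, pmax(p_adj, p_raw))
  out <- data.frame(group1 = gl[pairs[1, ]], group2 = gl[pairs[2, ]],
                    estimate = est, t = tt, df = dfree,
                    p_raw = p_raw, p_adj = p_adj)
  attr(out, "log_transform") <- log_transform
  attr(out, "zero_shift") <- shift
  attr(out, "n_draws") <- n_draws
  class(out) <- c("maxt_compare", "data.frame")
  out
}

#' @export
print.maxt_compare <- function(x, ...) {
  cat(sprintf("max-t simultaneous comparison (%s scale, %d pairs, %g null draws)\n",
              if (attr(x, "log_transform")) "log" else "raw",
              nrow(x), attr(x, "n_draws")))
  df <- as.data.frame(x)
  df$p_raw <- signif(df$p_raw, 3); df$p_adj <- signif(df$p_adj, 3)
  df$t <- round(df$t, 3); df$df <- round(df$df, 1)
  df$estimate <- signif(df$estimate, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (rank-then-Pearson).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return rho in [-1, 1]; NA with a warning for constant input.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

#' Two-sample two-sided Wilcoxon rank-sum test
#'
#' For small samples (combined n <= 20) the two-sided p-value is computed
#' by exact enumeration of all rank assignments (midranks for ties):
#' the proportion of assignments whose rank sum deviates from its null mean
#' at least as much as the observed one. Larger samples use the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples, each non-empty.
#' @return list with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `exact` flag.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (N <= 20) {
    cmb <- utils::combn(N, nx)
    sums <- colSums(matrix(r[cmb], nrow = nx))
    mu <- nx * (N + 1) / 2
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    return(list(statistic = U, p_value = p, exact = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = FALSE)
}
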