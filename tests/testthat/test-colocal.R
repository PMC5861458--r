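cluster_from <- function(x, y, photons = 1000, min_size = 1) {
  delaunay_segment(loc_table(data.frame(x = x, y = y, photons = photons,
                                        frame = seq_along(x) * 20)),
                   edge_threshold = 1e6, min_size = min_size)
}

test_that("weighted centroids are photon-weighted means", {
  # symmetric square, equal photons: geometric center
  cs <- cluster_from(c(0, 10, 0, 10), c(0, 0, 10, 10))
  cen <- weighted_centroid(cs)
  expect_equal(c(cen$x, cen$y), c(5, 5))
  # photons 1 at x=0 and 3 at x=4: weighted mean 3
  cs2 <- suppressWarnings(cluster_from(c(0, 4), c(0, 0), photons = c(1, 3)))
  expect_equal(weighted_centroid(cs2)$x, 3)
  # random cluster against the direct sum(w x)/sum(w) oracle
  set.seed(2)
  x <- runif(30); y <- runif(30); w <- runif(30, 1, 100)
  cs3 <- cluster_from(x, y, photons = w)
  cen3 <- weighted_centroid(cs3)
  expect_equal(cen3$x, sum(w * x) / sum(w))
  expect_equal(cen3$y, sum(w * y) / sum(w))
  # all-zero photons: unweighted mean with a warning
  cs4 <- suppressWarnings(cluster_from(c(0, 4), c(0, 0), photons = c(0, 0)))
  expect_warning(cen4 <- weighted_centroid(cs4), "photons")
  expect_equal(cen4$x, 2)
})

test_that("pair metrics match constructions and brute-force oracles", {
  # identical coincident clusters: c2c = p2p = 0
  x <- seq(0, 90, 10); y <- rep(0, 10)
  q <- cluster_from(x, y, min_size = 5)
  p <- cluster_from(x, y, min_size = 5)
  pm <- pair_clusters(q, p)
  expect_equal(pm$c2c_nm, 0)
  expect_equal(pm$p2p_nm, 0)
  expect_true(pm$colocalized)
  # two parallel 10-point lines 40 nm apart: p2p 40
  p2 <- cluster_from(x, y + 40, min_size = 5)
  pm2 <- pair_clusters(q, p2)
  expect_equal(pm2$p2p_nm, 40)
  expect_equal(pm2$c2c_nm, 40)
  # random scene: P2P equals the brute-force nearest-neighbor median
  set.seed(9)
  qx <- runif(25, 0, 100); qy <- runif(25, 0, 100)
  px <- runif(40, 50, 180); py <- runif(40, 50, 180)
  pm3 <- pair_clusters(cluster_from(qx, qy, min_size = 5),
                       cluster_from(px, py, min_size = 5),
                       both_directions = TRUE)
  oracle <- median(oracle_nn_dist(cbind(qx, qy), cbind(px, py)))
  expect_equal(pm3$p2p_nm, oracle)
  expect_equal(pm3$p2p_ba_nm,
               median(oracle_nn_dist(cbind(px, py), cbind(qx, qy))))
  # E2P never exceeds the worst member-to-partner distance
  expect_lte(pm3$e2p_nm, max(oracle_nn_dist(cbind(qx, qy), cbind(px, py))))
  # empty partner set: missing distances, flag false
  empty <- cluster_from(c(0, 1, 2), c(0, 0, 0), min_size = 10)
  pm4 <- pair_clusters(q, empty)
  expect_true(is.na(pm4$c2c_nm) && is.na(pm4$p2p_nm))
  expect_false(pm4$colocalized)
})

test_that("P2P is invariant under rigid motion of the scene", {
  set.seed(12)
  qx <- runif(20); qy <- runif(20); px <- runif(20) + 1; py <- runif(20)
  base <- pair_clusters(cluster_from(qx, qy, min_size = 5),
                        cluster_from(px, py, min_size = 5))$p2p_nm
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  qr <- cbind(qx, qy) %*% R; pr <- cbind(px, py) %*% R
  rot <- pair_clusters(cluster_from(qr[, 1] + 5, qr[, 2] - 3, min_size = 5),
                       cluster_from(pr[, 1] + 5, pr[, 2] - 3, min_size = 5))$p2p_nm
  expect_equal(rot, base, tolerance = 1e-9)
})

test_that("colocalization fractions count pairs below threshold per cell", {
  pm <- structure(data.frame(cluster = 1:4, partner = 1,
                             c2c_nm = c(50, 150, 199, 300),
                             p2p_nm = 0, e2p_nm = 0,
                             colocalized = c(TRUE, TRUE, TRUE, FALSE)),
                  class = c("pair_metrics", "data.frame"))
  fr <- coloc_fraction(pm)
  expect_equal(fr$fraction, 0.75)
  # all colocalized / none
  pm$colocalized <- TRUE
  expect_equal(coloc_fraction(pm)$fraction, 1)
  pm$colocalized <- FALSE
  expect_equal(coloc_fraction(pm)$fraction, 0)
  expect_warning(coloc_fraction(pm[0, ]), "no query clusters")
  # monotone in the C2C threshold by construction
  set.seed(3)
  qx <- runif(30, 0, 2000); qy <- runif(30, 0, 2000)
  px <- runif(30, 0, 2000); py <- runif(30, 0, 2000)
  fracs <- vapply(c(50, 100, 200, 400, 1e5), function(thr) {
    d <- oracle_nn_dist(cbind(qx, qy), cbind(px, py))
    mean(d < thr)
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("bivariate Ripley K matches its definition and CSR expectation", {
  roi <- roi_rect(2000, 2000)
  # one A point coincident with one B point: K = area for all r
  k <- ripley_bivariate(cbind(500, 500), cbind(500, 500),
                        radii = c(0, 100, 400), roi = roi)
  expect_equal(k, rep(roi$area, 3))
  # non-decreasing in r on a random scene
  set.seed(5)
  a <- roi_sample(roi, 40); b <- roi_sample(roi, 40)
  kk <- ripley_bivariate(a, b, seq(0, 500, 10), roi)
  expect_true(all(diff(kk) >= 0))
  # CSR mean: the uncorrected estimator's exact expectation in a square of
  # side L is A * P(d <= r) = pi r^2 - 8 r^3 / (3 L) + r^4 / (2 L^2), which
  # approaches pi r^2 as r/L -> 0 (no edge correction by design)
  r <- c(50, 150, 300); L <- 2000
  sims <- replicate(200, {
    ripley_bivariate(roi_sample(roi, 100), roi_sample(roi, 100), r, roi)
  })
  exact <- pi * r^2 - 8 * r^3 / (3 * L) + r^4 / (2 * L^2)
  expect_true(all(abs(rowMeans(sims) / exact - 1) < 0.05))
  expect_equal(rowMeans(sims)[1], pi * 50^2, tolerance = 0.06)
  # clustered A-near-B scene exceeds pi r^2 at small r
  a2 <- roi_sample(roi_rect(1800, 1800), 30)
  b2 <- a2 + matrix(rnorm(60, 0, 20 / sqrt(2)), 30)
  k2 <- ripley_bivariate(a2, b2, 50, roi)
  expect_gt(k2, pi * 50^2)
  expect_error(ripley_bivariate(a2[0, ], b2, 50, roi), "non-empty")
})

test_that("Ripley envelopes are reproducible, ordered, and detect planting", {
  roi <- roi_circle(1000)
  set.seed(8)
  a <- roi_sample(roi, 25)
  b <- a + matrix(rnorm(50, 0, 15), 25)
  inside <- roi_contains(roi, b[, 1], b[, 2])
  b[!inside, ] <- a[!inside, ]  # keep planted partners inside the ROI
  env1 <- ripley_envelope(a, b, seq(0, 300, 10), roi, n_rand = 50, seed = 123)
  env2 <- ripley_envelope(a, b, seq(0, 300, 10), roi, n_rand = 50, seed = 123)
  expect_identical(env1$observed, env2$observed)
  expect_identical(env1$env_lo, env2$env_lo)
  expect_identical(env1$env_hi, env2$env_hi)
  # envelope ordering invariant
  expect_true(all(env1$env_lo <= env1$env_mean + 1e-9))
  expect_true(all(env1$env_mean <= env1$env_hi + 1e-9))
  # planted pairing is classified as clustering
  expect_equal(env1$classification, "clustering")
  expect_error(ripley_envelope(a, b, 0:10, roi, n_rand = 1), "n_rand")
})
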