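test_that("3D Voronoi volumes are exact on a cubic lattice and flag the hull", {
  g <- seq(0, 40, by = 10)
  pts <- expand.grid(x = g, y = g, z = g)
  ann <- voronoi_annotate(loc_table(cbind(pts, photons = 1, frame = 0)))
  interior <- pts$x > 0 & pts$x < 40 & pts$y > 0 & pts$y < 40 &
    pts$z > 0 & pts$z < 40
  expect_true(all(ann$bounded[interior]))
  expect_equal(ann$volume[interior], rep(1000, sum(interior)),
               tolerance = 1e-9)  # lattice spacing^3
  expect_true(all(!ann$bounded[!interior]))  # hull-adjacent cells unbounded
  expect_true(all(is.infinite(ann$volume[!interior])))
})

test_that("degenerate 3D input suggests the 2D fallback, which matches deldir areas", {
  flat <- loc_table(data.frame(x = runif(10), y = runif(10), z = 0,
                               photons = 1, frame = 0))
  expect_error(voronoi_annotate(flat, dim = 3), "2D")
  expect_error(voronoi_annotate(flat[1:4, ], dim = 3), "at least 5")
  # 2D: interior cells of a square lattice have area spacing^2
  g <- seq(0, 40, by = 10)
  pts <- expand.grid(x = g, y = g)
  ann2 <- voronoi_annotate(loc_table(cbind(pts, photons = 1, frame = 0)),
                           dim = 2)
  interior <- pts$x > 0 & pts$x < 40 & pts$y > 0 & pts$y < 40
  expect_equal(ann2$volume[interior], rep(100, sum(interior)),
               tolerance = 1e-9)
})

test_that("Voronoi cell volume tracks inverse local density", {
  set.seed(11)
  # half dense cluster, half sparse background
  dense <- cbind(rnorm(300, 0, 100), rnorm(300, 0, 100), rnorm(300, 0, 100))
  sparse <- cbind(runif(300, -2000, 2000), runif(300, -2000, 2000),
                  runif(300, -2000, 2000))
  pts <- rbind(dense, sparse)
  tab <- loc_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                              photons = 1, frame = 0))
  ann <- voronoi_annotate(tab)
  # independent density estimate: distance to 10th nearest neighbor
  k10 <- FNN::get.knn(pts, k = 10)$nn.dist[, 10]
  ok <- ann$bounded
  rho <- spearman_rho(ann$volume[ok], k10[ok]^3)
  expect_gt(rho, 0.7)  # big cells where density is low
})

test_that("Voronoi filter applies the median rule and warns as specified", {
  ann <- structure(data.frame(volume = c(1, 2, 3, 4, 100),
                              bounded = TRUE),
                   class = c("voronoi_annotation", "data.frame"))
  mask <- voronoi_filter(ann, "auto")
  expect_equal(mask$keep, c(TRUE, TRUE, TRUE, FALSE, FALSE))  # median = 3
  expect_equal(attr(mask, "threshold"), 3)
  expect_equal(mask$reason[4], "voronoi")
  # manual threshold below the dataset minimum: empty keep set + warning
  expect_warning(m2 <- voronoi_filter(ann, 0.5), "band")
  expect_true(!any(m2$keep))
  # inside the mean/median band: silent
  expect_silent(voronoi_filter(ann, 10))
  # unbounded cells are always rejected
  ann$bounded[1] <- FALSE
  expect_false(voronoi_filter(ann, "auto")$keep[1])
})

test_that("the median Voronoi rule retains a dense cluster against 10x sparser background", {
  set.seed(21)
  # 600 cluster points at 10x the local density of 600 background points
  n <- 600
  cl <- cbind(rnorm(n, 0, 150), rnorm(n, 0, 150), rnorm(n, 0, 150))
  bg <- cbind(runif(n, -2000, 2000), runif(n, -2000, 2000),
              runif(n, -2000, 2000))
  tab <- loc_table(data.frame(x = c(cl[, 1], bg[, 1]), y = c(cl[, 2], bg[, 2]),
                              z = c(cl[, 3], bg[, 3]), photons = 1, frame = 0))
  mask <- voronoi_filter(voronoi_annotate(tab), "auto")
  kept_cluster <- mean(mask$keep[seq_len(n)])
  expect_gte(kept_cluster, 0.9)
})

test_that("neighbor filter applies the same/cross thresholds on closed balls", {
  # ring of exactly 30 same-channel neighbors at exactly 100 nm: kept (ties in)
  th <- seq(0, 2 * pi, length.out = 31)[-31]
  same <- data.frame(x = c(0, 100 * cos(th)), y = c(0, 100 * sin(th)), z = 0,
                     photons = 1, frame = 0)
  ta <- loc_table(same)
  res <- neighbor_filter(ta, NULL)
  expect_true(res$mask_a$keep[1])
  expect_equal(res$mask_a$n_same[1], 30)
  # remove one neighbor: rejected
  res2 <- neighbor_filter(ta[-2, ], NULL)
  expect_false(res2$mask_a$keep[1])
  # isolated localization with no neighbors at all: rejected
  iso <- loc_table(data.frame(x = c(0, 5000), y = 0, z = 0, photons = 1,
                              frame = 0))
  expect_false(any(neighbor_filter(iso, NULL)$mask_a$keep))
  # zero same-channel but 10 cross-channel neighbors: kept
  tb <- loc_table(data.frame(x = 10 * cos(th[1:10]), y = 10 * sin(th[1:10]),
                             z = 0, photons = 1, frame = 0, channel = "B"))
  single <- loc_table(data.frame(x = 0, y = 0, z = 0, photons = 1, frame = 0))
  both <- neighbor_filter(single, tb)
  expect_true(both$mask_a$keep[1])
  expect_equal(both$mask_a$n_cross[1], 10)
  expect_error(neighbor_filter(single, tb, radius = -1), "radius")
})

test_that("denoise masks are monotone in their thresholds", {
  set.seed(31)
  sc <- bundle_scene(31)
  tab <- sc$table
  ann <- voronoi_annotate(tab)
  med <- attr(voronoi_filter(ann, "auto"), "threshold")
  k1 <- voronoi_filter(ann, med)$keep
  k2 <- suppressWarnings(voronoi_filter(ann, med * 2)$keep)
  expect_true(all(k2[k1]))  # raising the volume threshold only adds keeps
  n1 <- neighbor_filter(tab, NULL, min_same = 30, min_cross = 10)$mask_a$keep
  n2 <- neighbor_filter(tab, NULL, min_same = 10, min_cross = 5)$mask_a$keep
  expect_true(all(n2[n1]))  # lowering neighbor minima only adds keeps
  # composition: whatever survives voronoi-then-neighbor was kept by voronoi
  kept_idx <- which(k1)
  nn <- neighbor_filter(tab[kept_idx, , drop = FALSE], NULL)$mask_a$keep
  final_idx <- kept_idx[nn]
  expect_true(all(k1[final_idx]))
  expect_true(all(final_idx %in% kept_idx))
})

test_that("pure CSR background is rejected at the default operating point", {
  set.seed(41)
  roi <- scene_roi()
  model <- imaging_model()  # 100 background localizations per um^2
  sc <- render_scene(list(), model, roi, seed = 42)
  tab <- sc$table
  ann <- voronoi_annotate(tab)
  keep_v <- voronoi_filter(ann, "auto")$keep
  kept <- tab[keep_v, , drop = FALSE]
  keep_n <- neighbor_filter(kept, NULL)$mask_a$keep
  rejection <- 1 - sum(keep_n) / nrow(tab)
  expect_gte(rejection, 0.9)
})

test_that("filament structure survives denoising with F1 >= 0.9", {
  sc <- filament_scene(51)
  tab <- add_precision(sc$table, 150, 160, 16)
  tab <- filter_quality(tab)
  tab <- link_frames(tab)
  keep_v <- voronoi_filter(voronoi_annotate(tab), "auto")$keep
  kept <- tab[keep_v, , drop = FALSE]
  keep_n <- neighbor_filter(kept, NULL)$mask_a$keep
  final <- kept[keep_n, , drop = FALSE]
  truth_final <- near_structure(final, sc)
  truth_all <- near_structure(tab, sc)
  tp <- sum(truth_final)
  precision <- tp / nrow(final)
  recall <- tp / sum(truth_all)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.9)
})
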