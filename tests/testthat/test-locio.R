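test_that("CSV round-trips are lossless and dialects agree", {
  df <- data.frame(x = c(100.5, 250), y = c(-30, 42.25), z = c(5, -12),
                   photons = c(1500, 2200), frame = c(3, 9),
                   channel = c("A", "B"))
  tab <- loc_table(df)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_localizations(tab, p1, "generic_csv")
  write_localizations(tab, p2, "thunderstorm_csv")
  back1 <- read_localizations(p1, "generic_csv")
  back2 <- read_localizations(p2, "thunderstorm_csv")
  expect_equal(nrow(back1), 2)
  for (col in c("x", "y", "z", "photons", "frame", "channel")) {
    expect_equal(back1[[col]], tab[[col]], info = col)
    expect_equal(back2[[col]], back1[[col]], info = col)
  }
})

test_that("missing mandatory columns are reported by name", {
  df <- data.frame(x_nm = 1, y_nm = 2, frame = 0)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_localizations(p, "generic_csv"), "photons")
  expect_error(loc_table(data.frame(x = 1, y = 2, photons = 10)), "frame")
})

test_that("Thompson precision matches an independent term-by-term evaluation", {
  # hand evaluation of the three variance terms
  N <- 1000; s <- 150; a <- 160; b <- 10
  t1 <- s^2 / N
  t2 <- a^2 / (12 * N)
  t3 <- 8 * pi * s^4 * b^2 / (a^2 * N^2)
  got <- thompson_precision(N, s, a, b)
  expect_equal(got$sigma_x, sqrt(t1 + t2 + t3))
  expect_equal(got$sigma, sqrt(2) * got$sigma_x)
  # shot-noise limit: background 0, vanishing pixel
  lim <- thompson_precision(400, 150, 1e-6, 0)
  expect_equal(lim$sigma_x, 150 / sqrt(400), tolerance = 1e-9)
  # combined sigma from per-axis values
  expect_equal(sqrt(7.07^2 + 7.07^2), 10.0, tolerance = 1e-3)
  expect_error(thompson_precision(0), "photons")
})

test_that("Thompson precision is monotone decreasing in photons", {
  ph <- seq(100, 10000, length.out = 50)
  sx <- thompson_precision(ph, 150, 160, 10)$sigma_x
  expect_true(all(diff(sx) < 0))
})

test_that("quality filter enforces photon and precision thresholds and is idempotent", {
  df <- data.frame(x = 1:4, y = 1:4, photons = c(999, 1000, 2000, 5000),
                   frame = 0:3, sigma_x = c(5, 5, 20, 5) / sqrt(2),
                   sigma_y = c(5, 5, 20, 5) / sqrt(2))
  tab <- loc_table(df)
  out <- filter_quality(tab)
  expect_equal(out$photons, c(1000, 5000))  # 999 photons and sigma 20 removed
  expect_equal(attr(out, "n_rejected"), 2)
  again <- filter_quality(out)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
  # identity on clean data, empty in / empty out
  clean <- loc_table(data.frame(x = 1:3, y = 1:3, photons = 2000, frame = 0,
                                sigma_x = 3, sigma_y = 3))
  expect_equal(nrow(filter_quality(clean)), 3)
  expect_equal(nrow(filter_quality(clean[0, ])), 0)
  nosig <- loc_table(data.frame(x = 1, y = 1, photons = 2000, frame = 0))
  expect_error(filter_quality(nosig), "thompson_precision")
})

test_that("frame linking merges blinking chains by the stated rules", {
  # one emitter on for frames 1-5: one record, photons summed
  df <- data.frame(x = 100 + rnorm(5, 0, 0.1), y = 50, photons = 1000,
                   frame = 1:5)
  out <- link_frames(loc_table(df))
  expect_equal(nrow(out), 1)
  expect_equal(out$photons, 5000)
  expect_equal(out$frame, 1)
  expect_equal(out$n_merged, 5)
  # gap beyond 10 frames: two records
  df2 <- data.frame(x = 100, y = 50, photons = 1000, frame = c(1, 13))
  expect_equal(nrow(link_frames(loc_table(df2))), 2)
  # within 10 frames: one record
  df3 <- data.frame(x = 100, y = 50, photons = 1000, frame = c(1, 11))
  expect_equal(nrow(link_frames(loc_table(df3))), 1)
  # two emitters 500 nm apart in the same frames stay distinct
  df4 <- data.frame(x = rep(c(0, 500), each = 3), y = 0, photons = 1000,
                    frame = rep(1:3, 2))
  expect_equal(nrow(link_frames(loc_table(df4))), 2)
  # different channels never merge
  df5 <- data.frame(x = 0, y = 0, photons = 1, frame = 1:2,
                    channel = c("A", "B"))
  expect_equal(nrow(link_frames(loc_table(df5))), 2)
  expect_error(link_frames(loc_table(df), link_radius = 0), "link_radius")
})

test_that("frame linking conserves photons and never increases counts", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    df <- data.frame(x = runif(n, 0, 2000), y = runif(n, 0, 2000),
                     photons = rlnorm(n, log(2000), 0.3),
                     frame = sample(1:500, n, replace = TRUE))
    tab <- loc_table(df)
    out <- link_frames(tab)
    expect_lte(nrow(out), nrow(tab))
    expect_equal(sum(out$photons), sum(tab$photons))
    expect_equal(sum(out$n_merged), n)
  }
})

test_that("channel registration is the least-squares translation", {
  a <- matrix(c(0, 0, 0, 100, 0, 0, 0, 100, 50), 3, byrow = TRUE)
  # pure offset recovered with opposite sign
  fs <- fiducial_set(a, sweep(a, 2, c(-10, 0, 0)))
  sh <- register_channels(fs)
  expect_equal(c(sh$dx, sh$dy, sh$dz), c(-10, 0, 0))
  expect_equal(register_channels(fiducial_set(a, a))$dx, 0)
  # noisy offsets: equals the mean per-pair displacement (direct oracle)
  set.seed(3)
  b <- a + matrix(rnorm(9, 5, 2), 3)
  sh2 <- register_channels(fiducial_set(a, b))
  expect_equal(c(sh2$dx, sh2$dy, sh2$dz), colMeans(a - b))
  # least-squares optimality vs any single-pair shift
  for (seed in 1:10) {
    set.seed(seed)
    aa <- matrix(runif(15, 0, 1000), 5)
    bb <- aa + matrix(rnorm(15, 2, 3), 5)
    opt <- register_channels(fiducial_set(aa, bb))
    rms <- function(s) sqrt(mean(rowSums((aa - sweep(bb, 2, -s))^2)))
    best <- rms(c(opt$dx, opt$dy, opt$dz))
    for (k in 1:5) expect_gte(rms(aa[k, ] - bb[k, ]) + 1e-9, best)
  }
  expect_error(fiducial_set(a, a[1:2, ]), "mismatched")
})
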